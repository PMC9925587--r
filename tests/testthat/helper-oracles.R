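# Independent oracles used to validate the fast implementations.

# O(N^2) exhaustive nearest-vertex scan in plain R.
brute_nn <- function(src, tgt) {
  idx <- integer(nrow(src))
  dist <- numeric(nrow(src))
  for (i in seq_len(nrow(src))) {
    d2 <- rowSums(sweep(tgt, 2L, src[i, ])^2)
    idx[i] <- which.min(d2)
    dist[i] <- sqrt(d2[idx[i]])
  }
  list(index = idx, distance = dist)
}

# Best mean nearest-neighbour cost over a coarse rigid grid: rotations every
# 5 degrees about each axis within +/- ang_range, translations on a 1 mm grid
# within +/- t_range.
grid_best_cost <- function(src, tgt, ang_range = 10, t_range = 2) {
  angs <- seq(-ang_range, ang_range, by = 5) * pi / 180
  ts <- seq(-t_range, t_range, by = 1)
  best <- Inf
  for (ax in angs) for (ay in angs) for (az in angs) {
    R <- axis_angle_rotation(c(1, 0, 0), ax) %*%
      axis_angle_rotation(c(0, 1, 0), ay) %*%
      axis_angle_rotation(c(0, 0, 1), az)
    rot <- src %*% t(R)
    for (tx in ts) for (ty in ts) for (tz in ts) {
      moved <- sweep(rot, 2L, c(tx, ty, tz), "+")
      cost <- mean(brute_nn(moved, tgt)$distance)
      if (cost < best) best <- cost
    }
  }
  best
}

# Monte-Carlo oracle for the nearest-point distance noise floor: two
# independently noised copies of the same cropped surface, no registration.
# Returns one mean distance per replicate.
noise_floor_oracle <- function(base_mesh, sigma, reps, seed, depth = 15) {
  axis <- estimate_axis(base_mesh)
  crop <- crop_below_plateau(base_mesh, axis, depth)
  vapply(seq_len(reps), function(r) {
    set.seed(seed + r)
    a <- crop$vertices + matrix(rnorm(3 * nrow(crop$vertices), 0, sigma), ncol = 3)
    b <- crop
    b$vertices <- b$vertices + matrix(rnorm(3 * nrow(crop$vertices), 0, sigma), ncol = 3)
    mean(nearest_correspondence(a, b, mode = "surface")$distances)
  }, 0)
}

rotation_err_deg <- function(Ra, Rb) {
  cosang <- (sum(diag(t(Ra) %*% Rb)) - 1) / 2
  acos(max(-1, min(1, cosang))) * 180 / pi
}
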