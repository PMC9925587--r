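# Geometric fixtures built in code.

tetra_mesh <- function() {
  triangle_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1L, 3L, 2L), c(1L, 2L, 4L), c(1L, 4L, 3L), c(2L, 3L, 4L)))
}

cube_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),   # bottom (-z)
             c(5, 6, 7), c(5, 7, 8),   # top (+z)
             c(1, 2, 6), c(1, 6, 5),   # front (-y)
             c(3, 4, 8), c(3, 8, 7),   # back (+y)
             c(4, 1, 5), c(4, 5, 8),   # left (-x)
             c(2, 3, 7), c(2, 7, 6))   # right (+x)
  triangle_mesh(v, f)
}

# Unit icosphere by icosahedron subdivision.
icosphere_mesh <- function(subdiv = 2L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- mid_cache[[key]]
      if (!is.null(got)) return(got)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      idx <- nrow(v)
      mid_cache[[key]] <- idx
      idx
    }
    nf <- matrix(0L, 0L, 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1L]; b <- f[k, 2L]; c_ <- f[k, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  triangle_mesh(v, f)
}

ellipsoid_mesh <- function(semi_axes = c(50, 20, 10), subdiv = 2L) {
  m <- icosphere_mesh(subdiv)
  m$vertices <- sweep(m$vertices, 2L, semi_axes, "*")
  m
}

random_tibia <- function(seed) {
  jit <- bisym:::with_seed(seed, runif(4L, 0.9, 1.1))
  generate_tibia(tibia_shape_params(
    shaft_length = 100 * jit[1L], plateau_width = 70 * jit[2L],
    plateau_depth = 48 * jit[3L], shaft_radius = 12 * jit[4L],
    mesh_resolution = 2L, seed = seed))
}

default_patch_spec <- function(noise_sigma = 0, seed = 1L,
                               magnitude = 1.6, radius = 8) {
  asymmetry_spec(
    patches = list(asym_patch("medial_plateau_posterior", radius, magnitude)),
    noise_sigma = noise_sigma,
    rigid_perturbation = random_rigid_transform(20, 10, seed = seed))
}

# Build a correspondence_set directly from a distance vector (for summary
# statistics tests); geometry is laid out so the stored invariants hold.
cs_from_distances <- function(d) {
  n <- length(d)
  src <- cbind(seq_len(n), 0, d)
  tgt <- cbind(seq_len(n), 0, 0)
  structure(list(source_indices = seq_len(n), source_points = src,
                 target_points = tgt, distances = as.numeric(d),
                 mask = rep(TRUE, n), mode = "vertex",
                 target_index = seq_len(n)),
            class = "correspondence_set")
}
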