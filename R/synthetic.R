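#' Shape parameters of the synthetic proximal tibia
#'
#' Controls the parametric generator: a tapering shaft blending into a
#' rounded-rectangle (superellipse) plateau capped by two smooth condylar
#' elevations of unequal height plus a tuberosity bulge. Units are mm. The
#' unequal condyles and the angularly offset tuberosity make the shape
#' genuinely chiral, as real tibias are: a true "right" can only be obtained
#' from a "left" by mirroring, never by rotation.
#'
#' @param shaft_length total bone length generated (mm).
#' @param shaft_radius shaft radius (mm).
#' @param plateau_width medio-lateral plateau width (mm).
#' @param plateau_depth antero-posterior plateau depth (mm).
#' @param condyle_heights heights of the (medial, lateral) condylar
#'   elevations (mm); unequal by default.
#' @param condyle_separation distance between condyle apices (mm).
#' @param tuberosity_offset outward bulge of the tibial tuberosity (mm).
#' @param mesh_resolution subdivision level (`>= 2`); level `k` gives
#'   `12 k` points per ring.
#' @param seed optional integer; adds a small smooth seeded radial
#'   modulation (sub-mm) so cohort subjects are individually distinct.
#' @return object of class `tibia_shape_params`.
#' @export
tibia_shape_params <- function(shaft_length = 100, shaft_radius = 12,
                               plateau_width = 70, plateau_depth = 48,
                               condyle_heights = c(7, 5),
                               condyle_separation = 34,
                               tuberosity_offset = 6,
                               mesh_resolution = 3L, seed = NULL) {
  stopifnot(shaft_length > 0, shaft_radius > 0, plateau_width > 0,
            plateau_depth > 0, all(condyle_heights > 0),
            condyle_separation > 0, tuberosity_offset >= 0,
            mesh_resolution >= 2)
  structure(list(shaft_length = shaft_length, shaft_radius = shaft_radius,
                 plateau_width = plateau_width, plateau_depth = plateau_depth,
                 condyle_heights = condyle_heights,
                 condyle_separation = condyle_separation,
                 tuberosity_offset = tuberosity_offset,
                 mesh_resolution = as.integer(mesh_resolution),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "tibia_shape_params")
}

#' Generate a synthetic right proximal tibia mesh
#'
#' Deterministic for fixed parameters (including the optional seed). The
#' frame is: `+z` proximal (long axis), `+x` medial, `+y` anterior; the
#' plateau sits at `z = shaft_length`. The mesh is closed with outward
#' winding (`signed_volume > 0`).
#'
#' @param params a [tibia_shape_params()].
#' @return a closed [triangle_mesh()].
#' @export
generate_tibia <- function(params = tibia_shape_params()) {
  stopifnot(inherits(params, "tibia_shape_params"))
  res <- params$mesh_resolution
  ntheta <- 12L * res
  nz <- 9L * res
  ncap <- 3L * res
  n_total <- (nz + 1L) * ntheta + (ncap - 1L) * ntheta + 2L
  if (n_total < 500L)
    stop("mesh_resolution too low to represent the condyles (< 500 vertices)")
  L <- params$shaft_length
  a <- params$plateau_width / 2
  b <- params$plateau_depth / 2
  rs <- params$shaft_radius
  theta <- 2 * pi * (seq_len(ntheta) - 1L) / ntheta
  p <- 4
  rho <- (abs(cos(theta))^p / a^p + abs(sin(theta))^p / b^p)^(-1 / p)

  # seeded smooth radial individuality (low-order harmonics, sub-mm)
  harm <- rep(1, ntheta)
  dome_gain <- 1
  if (!is.null(params$seed)) {
    mod <- with_seed(params$seed, {
      amps <- rnorm(3L, 0, 0.004)
      phis <- runif(3L, 0, 2 * pi)
      list(amps = amps, phis = phis, dome = 1 + rnorm(1L, 0, 0.03))
    })
    for (k in 1:3)
      harm <- harm * (1 + mod$amps[k] * cos((k + 1) * theta + mod$phis[k]))
    dome_gain <- mod$dome
  }

  flare <- 0.32 * L
  z0 <- L - flare
  th_t <- pi / 2 + 0.15
  z_t <- L - 0.30 * L
  dth <- atan2(sin(theta - th_t), cos(theta - th_t))

  ring_radius <- function(z) {
    u <- min(1, max(0, (z - z0) / flare))
    beta <- u * u * (3 - 2 * u)
    r <- (1 - beta) * rs + beta * rho
    r <- r + params$tuberosity_offset *
      exp(-dth^2 / (2 * 0.45^2) - (z - z_t)^2 / (2 * (0.12 * L)^2))
    r * harm
  }

  cond_c <- matrix(c(params$condyle_separation / 2, -2,
                     -params$condyle_separation / 2, -2), 2L, 2L, byrow = TRUE)
  cond_h <- params$condyle_heights * dome_gain
  r_c <- 0.48 * params$condyle_separation
  dome <- function(x, y) {
    out <- numeric(length(x))
    for (i in 1:2) {
      d <- sqrt((x - cond_c[i, 1L])^2 + (y - cond_c[i, 2L])^2)
      w <- ifelse(d < r_c, 0.5 * (1 + cos(pi * d / r_c)), 0)
      out <- out + cond_h[i] * w
    }
    out
  }

  verts <- matrix(0, n_total, 3L)
  # side rings
  for (j in 0:nz) {
    z <- L * j / nz
    r <- ring_radius(z)
    idx <- j * ntheta + seq_len(ntheta)
    verts[idx, ] <- cbind(r * cos(theta), r * sin(theta), z)
  }
  # top cap interior rings (rim ring is the topmost side ring)
  base_cap <- (nz + 1L) * ntheta
  rim_r <- ring_radius(L)
  for (m in seq_len(ncap - 1L)) {
    q <- (ncap - m) / ncap
    x <- q * rim_r * cos(theta)
    y <- q * rim_r * sin(theta)
    idx <- base_cap + (m - 1L) * ntheta + seq_len(ntheta)
    verts[idx, ] <- cbind(x, y, L + dome(x, y))
  }
  i_top_center <- base_cap + (ncap - 1L) * ntheta + 1L
  verts[i_top_center, ] <- c(0, 0, L + dome(0, 0))
  i_bot_center <- i_top_center + 1L
  verts[i_bot_center, ] <- c(0, 0, 0)

  faces <- vector("list", 4L)
  ip1 <- c(seq_len(ntheta - 1L) + 1L, 1L)  # i+1 with wraparound
  # side quads
  side <- vector("list", nz)
  for (j in 0:(nz - 1L)) {
    lo <- j * ntheta + seq_len(ntheta)
    hi <- (j + 1L) * ntheta + seq_len(ntheta)
    side[[j + 1L]] <- rbind(cbind(lo, lo[ip1], hi[ip1]),
                            cbind(lo, hi[ip1], hi))
  }
  faces[[1L]] <- do.call(rbind, side)
  # bottom fan (outward normal -z)
  ring0 <- seq_len(ntheta)
  faces[[2L]] <- cbind(i_bot_center, ring0[ip1], ring0)
  # cap ring quads (outward normal +z); ring m = 0 is the rim (side ring nz)
  cap_ring <- function(m) {
    if (m == 0L) nz * ntheta + seq_len(ntheta)
    else base_cap + (m - 1L) * ntheta + seq_len(ntheta)
  }
  cap <- vector("list", ncap)
  for (m in 0:(ncap - 2L)) {
    outer <- cap_ring(m)
    inner <- cap_ring(m + 1L)
    cap[[m + 1L]] <- rbind(cbind(outer, outer[ip1], inner[ip1]),
                           cbind(outer, inner[ip1], inner))
  }
  last <- cap_ring(ncap - 1L)
  cap[[ncap]] <- cbind(last, last[ip1], i_top_center)
  faces[[3L]] <- do.call(rbind, cap)
  fm <- do.call(rbind, faces[1:3])
  mesh <- triangle_mesh(verts, fm)
  if (signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

#' One localised asymmetry patch
#'
#' Displaces vertices within `radius` of the patch centre along the outward
#' vertex normal (or a fixed direction) by `magnitude` times a smooth cosine
#' falloff that reaches zero at the radius — deliberately free of cut-like
#' discontinuities.
#'
#' @param center either a 3-vector (mm, generator frame) or a named site on
#'   the deformed (left) mesh: `"medial_plateau_posterior"`,
#'   `"lateral_plateau"` or `"plateau_center"`.
#' @param radius patch radius (mm, `> 0`).
#' @param magnitude peak displacement (mm).
#' @param direction `"normal"` (outward vertex normal) or a fixed 3-vector.
#' @return object of class `asym_patch`.
#' @export
asym_patch <- function(center, radius, magnitude, direction = "normal") {
  stopifnot(radius > 0, is.numeric(magnitude), length(magnitude) == 1L)
  structure(list(center = center, radius = radius, magnitude = magnitude,
                 direction = direction), class = "asym_patch")
}

#' Injected asymmetry specification for a bilateral pair
#'
#' @param patches list of [asym_patch()] objects (empty = none).
#' @param global_scale_delta fractional size difference applied to the left
#'   side about its centroid (0 = none).
#' @param noise_sigma standard deviation of i.i.d. Gaussian vertex noise
#'   (mm), applied independently to both surfaces.
#' @param rigid_perturbation optional [rigid_transform()] applied to the
#'   left side (emulates arbitrary scanner pose).
#' @return object of class `asymmetry_spec`.
#' @export
asymmetry_spec <- function(patches = list(), global_scale_delta = 0,
                           noise_sigma = 0, rigid_perturbation = NULL) {
  stopifnot(noise_sigma >= 0,
            all(vapply(patches, inherits, TRUE, "asym_patch")))
  if (!is.null(rigid_perturbation))
    stopifnot(inherits(rigid_perturbation, "rigid_transform"))
  structure(list(patches = patches, global_scale_delta = global_scale_delta,
                 noise_sigma = noise_sigma,
                 rigid_perturbation = rigid_perturbation),
            class = "asymmetry_spec")
}

# Resolve a named patch site to a vertex coordinate on a left mesh in the
# generator frame (+z proximal; medial at -x after mirroring). Sites sit on
# the articular plateau surface, pulled inward from the rim: at a rim corner
# the nearest-feature assignment is discontinuous and a defect placed there
# would measure its own corner geometry rather than its magnitude.
resolve_patch_site <- function(mesh, site) {
  v <- mesh$vertices
  top <- which(v[, 3L] >= max(v[, 3L]) - 12)
  vt <- v[top, , drop = FALSE]
  nearest_to <- function(xy) {
    top[which.min((vt[, 1L] - xy[1L])^2 + (vt[, 2L] - xy[2L])^2)]
  }
  pick <- switch(site,
    medial_plateau_posterior = nearest_to(c(0.6 * min(vt[, 1L]),
                                            0.6 * min(vt[, 2L]))),
    lateral_plateau = nearest_to(c(0.6 * max(vt[, 1L]), 0)),
    plateau_center = top[which.max(vt[, 3L])],
    stop(sprintf("unknown patch site '%s'", site)))
  v[pick, ]
}

#' Generate a bilateral left/right pair with known ground truth
#'
#' The right side is a [generate_tibia()] mesh; the left is its mirror image
#' across the sagittal plane `x = 0`, optionally deformed by localised
#' patches, globally rescaled, perturbed by i.i.d. Gaussian vertex noise
#' (noise is also applied, independently, to the right side), and finally
#' moved by a rigid perturbation. The returned ground truth records the
#' per-vertex true displacement magnitudes and everything applied, against
#' which pipeline recovery is tested.
#'
#' @param params a [tibia_shape_params()].
#' @param spec an [asymmetry_spec()].
#' @param seed integer seed driving the noise draws.
#' @return list with elements `left`, `right` ([triangle_mesh()]) and
#'   `truth` (class `bilateral_ground_truth`: `spec`, `patch_centers`,
#'   `displacement` per left vertex in mm, `overlapping_patches`,
#'   `rigid_perturbation`, `noise_sigma`).
#' @export
make_bilateral_pair <- function(params = tibia_shape_params(),
                                spec = asymmetry_spec(), seed = 1L) {
  stopifnot(inherits(spec, "asymmetry_spec"))
  right <- generate_tibia(params)
  left <- mirror_across_plane(right, plane(c(0, 0, 0), c(1, 0, 0)))
  disp <- matrix(0, n_vertices(left), 3L)
  covered <- integer(n_vertices(left))
  centers <- list()
  if (length(spec$patches)) {
    nrm <- vertex_normals(left)
    for (p in spec$patches) {
      ctr <- if (is.character(p$center)) resolve_patch_site(left, p$center)
             else as.numeric(p$center)
      centers[[length(centers) + 1L]] <- ctr
      d <- sqrt(rowSums(sweep(left$vertices, 2L, ctr)^2))
      w <- ifelse(d < p$radius, 0.5 * (1 + cos(pi * d / p$radius)), 0)
      dirm <- if (identical(p$direction, "normal")) nrm
              else matrix(as.numeric(p$direction) /
                            sqrt(sum(as.numeric(p$direction)^2)),
                          n_vertices(left), 3L, byrow = TRUE)
      disp <- disp + (p$magnitude * w) * dirm
      covered <- covered + (w > 0)
    }
  }
  left$vertices <- left$vertices + disp
  if (spec$global_scale_delta != 0) {
    ctr <- colMeans(left$vertices)
    left$vertices <- sweep(sweep(left$vertices, 2L, ctr) *
                             (1 + spec$global_scale_delta), 2L, ctr, "+")
  }
  if (spec$noise_sigma > 0) {
    left$vertices <- left$vertices +
      with_seed(stage_seed(seed, "noise"),
                matrix(rnorm(3L * n_vertices(left), 0, spec$noise_sigma),
                       ncol = 3L))
    right$vertices <- right$vertices +
      with_seed(stage_seed(seed, "noise") + 1L,
                matrix(rnorm(3L * n_vertices(right), 0, spec$noise_sigma),
                       ncol = 3L))
  }
  if (!is.null(spec$rigid_perturbation))
    left <- apply_transform(left, spec$rigid_perturbation)
  truth <- structure(list(spec = spec,
                          patch_centers = centers,
                          displacement = sqrt(rowSums(disp^2)),
                          overlapping_patches = any(covered > 1L),
                          rigid_perturbation = spec$rigid_perturbation,
                          noise_sigma = spec$noise_sigma),
                     class = "bilateral_ground_truth")
  list(left = left, right = right, truth = truth)
}

#' Write a synthetic cohort of bilateral pairs
#'
#' Generates `n_subjects` left/right mesh pairs, writes them as binary PLY
#' together with a manifest CSV (`subject_id,left_path,right_path`) and a
#' ground-truth JSON, all reproducible from one master seed. By default
#' each subject's shape parameters are jittered a few percent around
#' `base_params` and given a subject-specific generator seed.
#'
#' @param n_subjects number of subjects (`>= 1`).
#' @param out_dir output directory (created if missing).
#' @param base_params a [tibia_shape_params()].
#' @param base_spec an [asymmetry_spec()] applied to every subject (or see
#'   `spec_sampler`).
#' @param master_seed integer master seed.
#' @param params_sampler optional `function(i, seed)` returning a
#'   [tibia_shape_params()]; default jitters lengths by +/-3%.
#' @param spec_sampler optional `function(i, seed)` returning an
#'   [asymmetry_spec()]; default returns `base_spec`.
#' @return invisibly, a list with `manifest` (data frame) and `truth`.
#' @export
make_cohort <- function(n_subjects, out_dir,
                        base_params = tibia_shape_params(),
                        base_spec = asymmetry_spec(),
                        master_seed = 1L,
                        params_sampler = NULL, spec_sampler = NULL) {
  stopifnot(n_subjects >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(params_sampler)) {
    params_sampler <- function(i, seed) {
      jit <- with_seed(seed, runif(4L, 0.97, 1.03))
      p <- base_params
      p$shaft_length <- p$shaft_length * jit[1L]
      p$plateau_width <- p$plateau_width * jit[2L]
      p$plateau_depth <- p$plateau_depth * jit[3L]
      p$shaft_radius <- p$shaft_radius * jit[4L]
      p$seed <- seed
      p
    }
  }
  if (is.null(spec_sampler)) spec_sampler <- function(i, seed) base_spec
  rows <- vector("list", n_subjects)
  truths <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%03d", i)
    seed_i <- stage_seed(master_seed, "cohort") + 131L * i
    pars <- params_sampler(i, seed_i)
    spc <- spec_sampler(i, seed_i + 1L)
    pair <- make_bilateral_pair(pars, spc, seed = seed_i + 2L)
    lp <- file.path(out_dir, paste0(sid, "_left.ply"))
    rp <- file.path(out_dir, paste0(sid, "_right.ply"))
    write_mesh(pair$left, lp)
    write_mesh(pair$right, rp)
    rows[[i]] <- data.frame(subject_id = sid, left_path = lp, right_path = rp,
                            stringsAsFactors = FALSE)
    truths[[i]] <- list(
      subject_id = sid,
      patches = lapply(seq_along(spc$patches), function(k) {
        p <- spc$patches[[k]]
        list(center = as.numeric(pair$truth$patch_centers[[k]]),
             radius = p$radius, magnitude = p$magnitude)
      }),
      noise_sigma = spc$noise_sigma,
      rigid_perturbation = if (is.null(spc$rigid_perturbation)) NULL else
        list(rotation = spc$rigid_perturbation$rotation,
             translation = spc$rigid_perturbation$translation))
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(truths, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(list(manifest = manifest, truth = truths))
}
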