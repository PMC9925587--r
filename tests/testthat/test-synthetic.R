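test_that("the generator is deterministic and well-oriented", {
  p <- tibia_shape_params(mesh_resolution = 2L, seed = 9L)
  a <- generate_tibia(p)
  b <- generate_tibia(p)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
  expect_gt(signed_volume(a), 0)
  expect_error(generate_tibia(tibia_shape_params(mesh_resolution = 1L)),
               "resolution")
})

test_that("the proximal end is wider than the shaft (axis sign driver)", {
  m <- generate_tibia(tibia_shape_params(plateau_width = 75, shaft_radius = 12,
                                         mesh_resolution = 2L))
  z <- m$vertices[, 3L]
  ctr <- colMeans(m$vertices)
  perp <- function(sel) {
    d <- sweep(m$vertices[sel, , drop = FALSE], 2L, ctr)
    sqrt(mean(d[, 1L]^2 + d[, 2L]^2))
  }
  expect_gt(perp(z >= stats::quantile(z, 0.9)), perp(z <= stats::quantile(z, 0.1)))
})

test_that("the shape is genuinely chiral (mirror realism)", {
  m <- generate_tibia(tibia_shape_params(mesh_resolution = 2L))
  mir <- mirror_across_plane(m, plane(c(0, 0, 0), c(1, 0, 0)))
  src <- subsample_points(mir, 400L, seed = 3L)
  tgt <- subsample_points(m, 400L, seed = 4L)
  pre <- prealign_pca(src, tgt)
  fit <- cpd_rigid(apply_transform(src, pre), tgt, cpd_config())
  tf <- compose_transform(fit$transform, pre)
  chiral_resid <- mean(nearest_correspondence(apply_transform(mir, tf), m,
                                              "surface")$distances)
  # symmetric baseline: the same cloud registered onto itself
  fit0 <- cpd_rigid(tgt, tgt, cpd_config())
  sym_resid <- mean(nearest_correspondence(
    apply_transform(m, fit0$transform), m, "surface")$distances)
  expect_gte(chiral_resid, 10 * max(sym_resid, 1e-3))
})

test_that("bilateral pairs record a faithful ground truth", {
  spec <- asymmetry_spec(
    patches = list(asym_patch("medial_plateau_posterior", 8, 1.6)),
    rigid_perturbation = random_rigid_transform(15, 10, seed = 2L))
  pp <- make_bilateral_pair(tibia_shape_params(mesh_resolution = 2L),
                            spec, seed = 3L)
  tr <- pp$truth
  expect_s3_class(tr, "bilateral_ground_truth")
  expect_true(all(tr$displacement >= 0))
  expect_equal(max(tr$displacement), 1.6, tolerance = 1e-12)
  # displacement is zero outside the patch footprint
  ctr <- tr$patch_centers[[1L]]
  right_mir <- mirror_across_plane(pp$right, plane(c(0, 0, 0), c(1, 0, 0)))
  d_to_ctr <- sqrt(rowSums(sweep(right_mir$vertices, 2L, ctr)^2))
  expect_true(all(tr$displacement[d_to_ctr > 8] == 0))
  expect_false(tr$overlapping_patches)
  # overlapping patches are allowed and flagged
  spec2 <- asymmetry_spec(patches = list(
    asym_patch("medial_plateau_posterior", 8, 1),
    asym_patch("medial_plateau_posterior", 8, 0.5)))
  pp2 <- make_bilateral_pair(tibia_shape_params(mesh_resolution = 2L),
                             spec2, seed = 3L)
  expect_true(pp2$truth$overlapping_patches)
})

test_that("cohort generation is reproducible and rank-preserving", {
  od1 <- withr::local_tempdir()
  od2 <- withr::local_tempdir()
  make_cohort(3L, od1, base_params = tibia_shape_params(mesh_resolution = 2L),
              master_seed = 5L)
  make_cohort(3L, od2, base_params = tibia_shape_params(mesh_resolution = 2L),
              master_seed = 5L)
  m1 <- readLines(file.path(od1, "manifest.csv"))
  m2 <- readLines(file.path(od2, "manifest.csv"))
  expect_identical(gsub(od1, "", m1, fixed = TRUE),
                   gsub(od2, "", m2, fixed = TRUE))
  a <- read_mesh(file.path(od1, "S002_left.ply"))
  b <- read_mesh(file.path(od2, "S002_left.ply"))
  expect_identical(a$vertices, b$vertices)

  # per-subject reported maxima preserve the injected magnitude order
  mags <- c(0.5, 1.0, 1.6)
  maxes <- vapply(seq_along(mags), function(i) {
    spec <- asymmetry_spec(patches = list(
      asym_patch("medial_plateau_posterior", 8, mags[i])))
    pp <- make_bilateral_pair(tibia_shape_params(mesh_resolution = 2L),
                              spec, seed = 10L + i)
    run_subject(pp$left, pp$right, run_config(seed = i))$max_mm
  }, 0)
  expect_identical(order(maxes), order(mags))
  expect_equal(maxes[3L], 1.6, tolerance = 0.1)
})
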