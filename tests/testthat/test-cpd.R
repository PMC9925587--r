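test_that("surface subsampling is seeded, area-weighted and on-surface", {
  m <- random_tibia(2L)
  a <- subsample_points(m, 200L, seed = 42L)
  b <- subsample_points(m, 200L, seed = 42L)
  expect_identical(a, b)
  expect_error(subsample_points(m, 3L), "at least 4")

  # two triangles with areas 9:1 -> counts approach 9:1 (binomial, 3 sigma)
  two <- triangle_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0),
                             c(10, 0, 0), c(11, 0, 0), c(10, 1, 0)),
                       rbind(c(1L, 2L, 3L), c(4L, 5L, 6L)))
  pts <- subsample_points(two, 2000L, seed = 7L)
  n_big <- sum(attr(pts, "triangle") == 1L)
  expect_gt(n_big, 1800 - 3 * sqrt(2000 * 0.9 * 0.1))
  expect_lt(n_big, 1800 + 3 * sqrt(2000 * 0.9 * 0.1))

  # sampled points lie on the mesh surface
  tet <- tetra_mesh()
  p4 <- subsample_points(tet, 4L, seed = 1L)
  d <- nearest_correspondence(p4, tet, mode = "surface")$distances
  expect_lt(max(d), 1e-12)
})

test_that("CPD on identical clouds returns the identity", {
  pts <- subsample_points(random_tibia(1L), 300L, seed = 3L)
  fit <- cpd_rigid(pts, pts, cpd_config())
  expect_lt(max(abs(fit$transform$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(fit$transform$translation)), 1e-6)
  expect_equal(fit$scale, 1.0)
})

test_that("CPD recovers a known rigid transform, also under outliers", {
  pts <- subsample_points(random_tibia(4L), 500L, seed = 5L)
  R0 <- axis_angle_rotation(c(0, 0, 1), 10 * pi / 180)
  t0 <- c(5, 0, 0)
  truth <- rigid_transform(R0, t0)
  tgt <- apply_transform(pts, truth)
  fit <- cpd_rigid(pts, tgt, cpd_config())
  expect_lt(rotation_err_deg(fit$transform$rotation, R0) * pi / 180, 1e-3)
  expect_lt(sqrt(sum((fit$transform$translation - t0)^2)), 1e-3)

  # 20% uniform outliers appended to the target, w = 0.2
  out <- bisym:::with_seed(9L, matrix(runif(300L, -60, 60), ncol = 3L))
  out <- sweep(out, 2L, colMeans(tgt), "+")
  fit2 <- cpd_rigid(pts, rbind(tgt, out), cpd_config(w = 0.2))
  expect_lt(rotation_err_deg(fit2$transform$rotation, R0), 0.5)
  expect_lt(sqrt(sum((fit2$transform$translation - t0)^2)), 0.2)
})

test_that("the CPD objective is non-increasing and rotations stay proper", {
  for (s in 1:5) {
    pts <- subsample_points(random_tibia(s), 300L, seed = s)
    truth <- random_rigid_transform(30, 20, seed = s + 10L)
    noise <- bisym:::with_seed(s + 20L,
                               matrix(rnorm(900L, 0, 0.2), ncol = 3L))
    fit <- cpd_rigid(pts, apply_transform(pts, truth) + noise, cpd_config())
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-8 * pmax(1, abs(tr[-length(tr)]))))
    expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-8)
  }
})

test_that("registration never absorbs the chirality flip", {
  m <- generate_tibia(tibia_shape_params(mesh_resolution = 2L))
  mir <- mirror_across_plane(m, plane(c(0, 0, 0), c(1, 0, 0)))
  src <- subsample_points(mir, 400L, seed = 1L)
  tgt <- subsample_points(m, 400L, seed = 2L)
  pre <- prealign_pca(src, tgt)
  fit <- cpd_rigid(apply_transform(src, pre), tgt, cpd_config())
  tf <- compose_transform(fit$transform, pre)
  resid <- mean(nearest_correspondence(apply_transform(mir, tf), m,
                                       mode = "surface")$distances)
  # the shape is genuinely chiral: a proper-rigid fit leaves a large residual
  expect_gt(resid, 0.1)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-8)
})

test_that("CPD matches an exhaustive coarse grid search on tiny instances", {
  pts <- bisym:::with_seed(11L, matrix(runif(30L, -10, 10), ncol = 3L))
  truth <- rigid_transform(
    axis_angle_rotation(c(0.3, -0.5, 0.81), 8 * pi / 180), c(1.2, -0.8, 0.5))
  tgt <- apply_transform(pts, truth)
  fit <- cpd_rigid(pts, tgt, cpd_config(w = 0))
  cpd_cost <- mean(brute_nn(apply_transform(pts, fit$transform), tgt)$distance)
  expect_lte(cpd_cost, grid_best_cost(pts, tgt) + 1e-6)
})

test_that("apply_transform obeys identity, translation and inversion", {
  pts <- matrix(c(0, 0, 0, 1, 2, 3), ncol = 3L, byrow = TRUE)
  expect_equal(apply_transform(pts, rigid_transform()), pts, tolerance = 0)
  tr <- rigid_transform(diag(3), c(1, 1, 1))
  expect_equal(apply_transform(pts[1L, , drop = FALSE], tr),
               matrix(c(1, 1, 1), 1L), tolerance = 0)
  tf <- random_rigid_transform(60, 30, seed = 3L)
  back <- apply_transform(apply_transform(pts, tf), invert_transform(tf))
  expect_lt(max(abs(back - pts)), 1e-9)
  # reflections are rejected at construction
  expect_error(rigid_transform(diag(c(-1, 1, 1))), "proper")
  expect_error(cpd_rigid(pts, pts, cpd_config()), "at least 4")
})
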