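test_that("reflection follows the plane formula", {
  m <- triangle_mesh(rbind(c(1, 2, 3), c(0, 0, 0), c(0, 1, 0)),
                     rbind(c(1L, 2L, 3L)))
  r <- mirror_across_plane(m, plane(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(r$vertices[1L, ], c(-1, 2, 3))
  # offset plane x = 2
  r2 <- mirror_across_plane(m, plane(c(2, 0, 0), c(1, 0, 0)))
  expect_equal(r2$vertices[1L, ], c(3, 2, 3))
})

test_that("mirroring is an involution on random meshes", {
  for (s in 1:5) {
    m <- random_tibia(s)
    pl <- plane(bisym:::with_seed(s, rnorm(3L, 0, 20)),
                bisym:::with_seed(s + 50L, rnorm(3L)))
    back <- mirror_across_plane(mirror_across_plane(m, pl), pl)
    expect_lt(max(abs(back$vertices - m$vertices)), 1e-12)
    expect_identical(back$faces, m$faces)
  }
})

test_that("default sagittal plane normal is the shortest covariance axis", {
  e <- ellipsoid_mesh(c(50, 20, 10))
  pl <- default_sagittal_plane(e)
  expect_equal(abs(pl$normal[3L]), 1, tolerance = 1e-6)
  # translation equivariance: same normal, plane point shifts along
  e2 <- e
  e2$vertices <- sweep(e2$vertices, 2L, c(100, 0, 0), "+")
  pl2 <- default_sagittal_plane(e2)
  expect_equal(pl2$normal, pl$normal, tolerance = 1e-9)
  expect_equal(pl2$point - pl$point, c(100, 0, 0), tolerance = 1e-9)
})

test_that("degenerate vertex sets are rejected, spheres still succeed", {
  line <- triangle_mesh(cbind(1:5, 0, 0) + 0, matrix(integer(), 0L, 3L))
  expect_error(default_sagittal_plane(line), "collinear")
  # a sphere has no preferred plane but the call must still succeed
  pl <- default_sagittal_plane(icosphere_mesh(1L))
  expect_equal(sum(pl$normal^2), 1, tolerance = 1e-9)
})

test_that("the mirror plane choice does not move the symmetry distances", {
  pp <- make_bilateral_pair(tibia_shape_params(mesh_resolution = 2L), seed = 31L)
  base <- run_subject(pp$left, pp$right, run_config(seed = 7L))
  alt1 <- run_subject(pp$left, pp$right,
                      run_config(seed = 7L,
                                 mirror_plane = plane(c(0, 0, 0), c(1, 0, 0))))
  alt2 <- run_subject(pp$left, pp$right,
                      run_config(seed = 7L,
                                 mirror_plane = plane(c(5, -3, 40), c(1, 1, 0.5))))
  expect_lt(abs(alt1$mean_mm - base$mean_mm), 2e-3)
  expect_lt(abs(alt2$mean_mm - base$mean_mm), 2e-3)
})
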