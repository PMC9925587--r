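test_that("nearest correspondence computes Euclidean distances", {
  tgt <- triangle_mesh(rbind(c(0, 0, 2), c(1, 0, 2), c(0, 1, 2)),
                       rbind(c(1L, 2L, 3L)))
  cs <- nearest_correspondence(rbind(c(0, 0, 0)), tgt, mode = "vertex")
  expect_equal(cs$distances, 2.0)
  # identity: source equals target vertices
  m <- random_tibia(5L)
  cs0 <- nearest_correspondence(m$vertices, m, mode = "vertex")
  expect_true(all(cs0$distances == 0))
  expect_true(all(cs0$mask))
  expect_error(nearest_correspondence(matrix(numeric(), 0L, 3L), m), "empty")
})

test_that("vertex-mode distances equal the exhaustive O(N^2) scan exactly", {
  for (s in 1:5) {
    n <- bisym:::with_seed(s, sample(20:200, 2L))
    src <- bisym:::with_seed(s + 100L, matrix(runif(3 * n[1L], -50, 50), ncol = 3L))
    tgtv <- bisym:::with_seed(s + 200L, matrix(runif(3 * n[2L], -50, 50), ncol = 3L))
    tgt <- triangle_mesh(tgtv, matrix(integer(), 0L, 3L))
    cs <- nearest_correspondence(src, tgt, mode = "vertex")
    oracle <- brute_nn(src, tgtv)
    expect_equal(cs$distances, oracle$distance, tolerance = 1e-13)
    expect_identical(cs$target_index, oracle$index)
  }
})

test_that("surface mode projects onto triangles, not just vertices", {
  tgt <- triangle_mesh(rbind(c(-1, -1, 0), c(3, -1, 0), c(0, 3, 0)),
                       rbind(c(1L, 2L, 3L)))
  cs <- nearest_correspondence(rbind(c(0, 0, 1)), tgt, mode = "surface")
  expect_equal(cs$distances, 1.0, tolerance = 1e-12)  # foot inside the face
  expect_equal(cs$target_points[1L, ], c(0, 0, 0), tolerance = 1e-12)
  # beyond an edge the distance is to the closest edge/corner
  cs2 <- nearest_correspondence(rbind(c(-2, -2, 0)), tgt, mode = "surface")
  expect_equal(cs2$distances, sqrt(2), tolerance = 1e-12)
})

test_that("cut-edge masking separates edge artifacts from true distances", {
  m <- generate_tibia(tibia_shape_params(mesh_resolution = 2L))
  ax <- estimate_axis(m)
  crop <- crop_below_plateau(m, ax, depth = 15)
  cs <- nearest_correspondence(crop$vertices, crop, mode = "vertex")
  # band 0 is a no-op
  expect_identical(mask_cut_edge(cs, ax, depth = 15, band = 0)$mask, cs$mask)
  # inject an artificial spike at the cut edge only
  proj <- as.numeric(crop$vertices %*% ax$direction)
  edge <- proj <= ax$plateau_level - 15 + 4
  expect_gt(sum(edge), 0)
  cs$distances[edge] <- 5
  masked <- mask_cut_edge(cs, ax, depth = 15, band = 4)
  expect_true(all(!masked$mask[edge]))
  sm <- subject_summary(masked, use_mask = TRUE)
  expect_lt(sm$masked$mean_mm, sm$raw$mean_mm)
  # all points masked -> masked summary is an explicit error
  cs_all <- cs
  cs_all$mask <- rep(FALSE, length(cs_all$mask))
  expect_error(subject_summary(cs_all, use_mask = TRUE), "masked")
})

test_that("summary statistics match hand arithmetic and moments", {
  sm <- subject_summary(cs_from_distances(c(3, 4)))
  expect_equal(sm$mean_mm, 3.5)
  expect_equal(sm$rms_mm, sqrt(12.5))
  expect_equal(sm$max_mm, 4)
  expect_equal(sm$max_index, 2L)
  expect_equal(unname(sm$percentiles[1L]), 3.5)

  z <- subject_summary(cs_from_distances(rep(0, 10)))
  expect_equal(c(z$mean_mm, z$rms_mm, z$max_mm), c(0, 0, 0))

  # |N(0, 0.3)| has RMS exactly sigma; 1000 draws stay in the 3-sigma band
  d <- abs(bisym:::with_seed(77L, rnorm(1000L, 0, 0.3)))
  expect_gt(subject_summary(cs_from_distances(d))$rms_mm, 0.27)
  expect_lt(subject_summary(cs_from_distances(d))$rms_mm, 0.33)
})

test_that("heatmap fields attach, localize and survive PLY round-trips", {
  m <- random_tibia(6L)
  cs <- nearest_correspondence(m$vertices, m, mode = "vertex")
  hm <- heatmap_field(m, cs)
  expect_equal(hm$fields$distance_mm, rep(0, n_vertices(m)))
  expect_equal(hm$fields$mask, rep(1, n_vertices(m)))
  hm$fields$distance_mm[17L] <- 1.6
  p <- withr::local_tempfile(fileext = ".ply")
  write_mesh(hm, p)
  back <- read_mesh(p)
  expect_lt(max(abs(back$fields$distance_mm - hm$fields$distance_mm)), 1e-6)
  expect_error(heatmap_field(m, cs_from_distances(c(1, 2))), "per source vertex")
})

test_that("directed mean distances are bounded by the Hausdorff distance", {
  for (s in 1:4) {
    a <- random_tibia(s)
    b <- random_tibia(s + 40L)
    h <- hausdorff_vertex(a, b)
    expect_lte(mean(nearest_correspondence(a$vertices, b, "vertex")$distances), h)
    expect_lte(mean(nearest_correspondence(b$vertices, a, "vertex")$distances), h)
  }
})
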