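test_that("axis estimation finds the long axis with the wide end proximal", {
  m <- generate_tibia(tibia_shape_params(mesh_resolution = 2L))
  ax <- estimate_axis(m)
  # generator long axis is +z, plateau (wide end) at the top
  ang <- acos(min(1, abs(sum(ax$direction * c(0, 0, 1))))) * 180 / pi
  expect_lt(ang, 2)
  expect_gt(sum(ax$direction * c(0, 0, 1)), 0)
  expect_equal(ax$plateau_level,
               max(m$vertices %*% ax$direction), tolerance = 0)

  # equivariance under rotation
  tf <- random_rigid_transform(180, 50, seed = 8L)
  m2 <- apply_transform(m, tf)
  ax2 <- estimate_axis(m2)
  mapped <- as.numeric(tf$rotation %*% ax$direction)
  ang2 <- acos(min(1, abs(sum(ax2$direction * mapped)))) * 180 / pi
  expect_lt(ang2, 2)

  # isotropic cloud is ambiguous without a hint
  expect_error(estimate_axis(icosphere_mesh(1L)), "ambiguous")
  axh <- estimate_axis(icosphere_mesh(1L), proximal_hint = c(0, 0, 1))
  expect_gte(sum(axh$direction * c(0, 0, 1)), 0)
})

test_that("crop keeps exactly the faces fully above the cut plane", {
  v <- rbind(c(0, 0, 0), c(1, 0, -5), c(0, 1, -14.9), c(0, -1, -15.1))
  m <- triangle_mesh(v, rbind(c(1L, 2L, 3L), c(2L, 3L, 4L)))
  ax <- user_axis(m, c(0, 0, 1))  # plateau_level = 0
  cr <- crop_below_plateau(m, ax, depth = 15)
  expect_equal(n_vertices(cr), 3L)
  expect_equal(n_faces(cr), 1L)
  expect_equal(attr(cr, "orig_vertex_index"), 1:3)
})

test_that("crop containment, idempotence and degenerate depths", {
  m <- generate_tibia(tibia_shape_params(shaft_length = 80,
                                         mesh_resolution = 2L))
  ax <- estimate_axis(m)
  cr <- crop_below_plateau(m, ax, depth = 15)
  proj <- as.numeric(cr$vertices %*% ax$direction)
  expect_true(all(proj >= ax$plateau_level - 15))
  expect_true(all(proj <= ax$plateau_level))
  # retained extent is bounded by depth + the longest edge
  e <- m$vertices[m$faces[, 1L], ] - m$vertices[m$faces[, 2L], ]
  longest <- sqrt(max(rowSums(e^2)))
  expect_lte(diff(range(proj)), 15 + longest)
  # idempotence with the same axis and depth
  cr2 <- crop_below_plateau(cr, ax, depth = 15)
  expect_equal(cr2$vertices, cr$vertices, tolerance = 0)
  expect_identical(cr2$faces, cr$faces)
  # huge depth is a no-op
  all_m <- crop_below_plateau(m, ax, depth = 1e6)
  expect_equal(n_vertices(all_m), n_vertices(m))
  expect_equal(n_faces(all_m), n_faces(m))
  # cut above the whole mesh
  ax_hi <- ax
  ax_hi$plateau_level <- ax$plateau_level + 1000
  expect_error(crop_below_plateau(m, ax_hi, depth = 10), "empty")
})
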