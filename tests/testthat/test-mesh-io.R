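test_that("PLY round-trips geometry, faces and scalar fields", {
  m <- tetra_mesh()
  m$fields$distance_mm <- c(0.5, 1.25, 2, 0)
  for (binary in c(TRUE, FALSE)) {
    p <- withr::local_tempfile(fileext = ".ply")
    write_mesh(m, p, binary = binary)
    m2 <- read_mesh(p)
    expect_equal(n_vertices(m2), 4L)
    expect_equal(n_faces(m2), 4L)
    expect_identical(m2$faces, m$faces)
    expect_lt(max(abs(m2$vertices - m$vertices)), 1e-6)
    expect_lt(max(abs(m2$fields$distance_mm - m$fields$distance_mm)), 1e-6)
  }
  # the field is stored as a named per-vertex property
  p <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, p)
  hdr <- readLines(p, n = 12L, warn = FALSE)
  expect_true(any(grepl("property float distance_mm", hdr)))
})

test_that("OBJ round-trips geometry within 1e-6 mm", {
  m <- random_tibia(3L)
  p <- withr::local_tempfile(fileext = ".obj")
  write_mesh(m, p)
  m2 <- read_mesh(p)
  expect_identical(m2$faces, m$faces)
  expect_lt(max(abs(m2$vertices - m$vertices)), 1e-6)
})

test_that("STL reading merges the triangle soup back into a coherent mesh", {
  m <- tetra_mesh()
  for (binary in c(TRUE, FALSE)) {
    p <- withr::local_tempfile(fileext = ".stl")
    write_mesh(m, p, binary = binary)
    m2 <- read_mesh(p)
    expect_equal(n_vertices(m2), 4L)   # soup corners merged
    expect_equal(n_faces(m2), 4L)
    expect_equal(abs(signed_volume(m2)), 1 / 6, tolerance = 1e-5)
  }
})

test_that("STL drops scalar fields with a warning (format limitation)", {
  m <- tetra_mesh()
  m$fields$distance_mm <- rep(1, 4L)
  p <- withr::local_tempfile(fileext = ".stl")
  expect_warning(write_mesh(m, p), "geometry only")
  expect_null(read_mesh(p)$fields$distance_mm)
})

test_that("I/O errors name the offending path", {
  expect_error(read_mesh("/nonexistent/mesh.ply"), "/nonexistent/mesh.ply")
  p <- withr::local_tempfile(fileext = ".ply")
  full <- withr::local_tempfile(fileext = ".ply")
  write_mesh(random_tibia(1L), full)
  writeBin(readBin(full, "raw", 300L), p)
  expect_error(read_mesh(p), "truncated|not a valid PLY")
  # non-mesh text content
  p2 <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("hello", "world"), p2)
  expect_error(read_mesh(p2), "PLY")
})
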