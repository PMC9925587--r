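#' Oriented plane in 3D
#'
#' @param point a 3-vector on the plane (mm).
#' @param normal a nonzero 3-vector; normalised to unit length.
#' @return object of class `bisym_plane`.
#' @export
plane <- function(point, normal) {
  point <- as.numeric(point)
  normal <- as.numeric(normal)
  stopifnot(length(point) == 3L, length(normal) == 3L,
            all(is.finite(point)), all(is.finite(normal)))
  len <- sqrt(sum(normal^2))
  if (len < 1e-12) stop("plane normal must be nonzero")
  structure(list(point = point, normal = normal / len), class = "bisym_plane")
}

#' Reflect a mesh across a plane
#'
#' Maps each vertex `v` to `v - 2 ((v - p) . n) n`. Reflection flips spatial
#' chirality; with `repair_winding = TRUE` (default) each face's vertex order
#' is reversed so that outward surface orientation is retained and
#' [signed_volume()] keeps its sign. Scalar fields are carried over.
#'
#' @param mesh a [triangle_mesh()].
#' @param plane a [plane()].
#' @param repair_winding reverse face winding to retain outward orientation.
#' @return the reflected [triangle_mesh()].
#' @export
mirror_across_plane <- function(mesh, plane, repair_winding = TRUE) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(plane, "bisym_plane"))
  n <- plane$normal
  d <- (mesh$vertices %*% n) - sum(plane$point * n)
  v <- mesh$vertices - 2 * (d %*% t(n))
  f <- mesh$faces
  if (repair_winding && nrow(f) > 0L) f <- f[, c(1L, 3L, 2L), drop = FALSE]
  triangle_mesh(v, f, mesh$fields)
}

#' Default sagittal mirror plane of a mesh
#'
#' The plane through the mesh centroid whose normal is the shortest principal
#' axis of the vertex covariance — a generic "side-to-side" direction. Any
#' choice of mirror plane differs from any other by a rigid motion that the
#' subsequent registration absorbs, so only the chirality flip matters for the
#' pipeline; this construction is deterministic and needs no anatomical
#' landmarks. The normal's sign is fixed by making its first
#' largest-magnitude component positive.
#'
#' @param mesh a [triangle_mesh()] with at least 3 non-collinear vertices.
#' @return a [plane()].
#' @export
default_sagittal_plane <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  if (nrow(v) < 3L) stop("mesh has fewer than 3 vertices")
  ctr <- colMeans(v)
  cv <- stats::cov(v)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2L] <= max(eg$values[1L], 1) * 1e-12)
    stop("degenerate (collinear) vertex set: no plane is defined")
  nrm <- eg$vectors[, 3L]
  k <- which.max(abs(nrm))
  if (nrm[k] < 0) nrm <- -nrm
  if (abs(eg$values[2L] - eg$values[3L]) < 1e-9 * max(eg$values[1L], 1))
    message("mirror plane: shortest covariance axis is degenerate; tie broken by eigen-solver order")
  plane(ctr, nrm)
}
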