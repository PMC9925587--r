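#' Triangle mesh container
#'
#' The universal surface representation used throughout the package: an
#' `n x 3` matrix of vertex coordinates in millimetres, an `f x 3` integer
#' matrix of 1-based vertex indices (one triangle per row), and optionally
#' named per-vertex scalar fields such as `"distance_mm"`.
#'
#' Invariants enforced at construction: all coordinates finite; every face
#' index in `[1, n]`; no face repeats a vertex; each scalar field has exactly
#' one value per vertex.
#'
#' @param vertices numeric matrix (`n x 3`), coordinates in mm.
#' @param faces integer matrix (`f x 3`), 1-based vertex indices.
#' @param fields named list of numeric per-vertex scalar fields (optional).
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, fields = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L)
    stop("vertices must be an n x 3 matrix")
  if (!all(is.finite(vertices)))
    stop("mesh invariant violated: non-finite vertex coordinates")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (nrow(faces) > 0L) {
    if (ncol(faces) != 3L)
      stop("faces must be an f x 3 matrix of vertex indices")
    n <- nrow(vertices)
    if (min(faces) < 1L || max(faces) > n)
      stop("mesh invariant violated: face index out of range [1, n_vertices]")
    degen <- faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
      faces[, 2L] == faces[, 3L]
    if (any(degen))
      stop("mesh invariant violated: face repeats a vertex index")
  }
  if (length(fields)) {
    if (is.null(names(fields)) || any(names(fields) == ""))
      stop("scalar fields must be named")
    for (nm in names(fields)) {
      fields[[nm]] <- as.numeric(fields[[nm]])
      if (length(fields[[nm]]) != nrow(vertices))
        stop(sprintf("scalar field '%s' must have one value per vertex", nm))
    }
  }
  structure(list(vertices = vertices, faces = faces, fields = fields),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces", nrow(x$vertices),
              nrow(x$faces)))
  if (length(x$fields))
    cat(sprintf(", fields: %s", paste(names(x$fields), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Number of vertices / faces of a mesh
#' @param mesh a [triangle_mesh()].
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' Signed enclosed volume of a triangle mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes spanned by each face
#' and the origin. For a closed mesh with outward-wound faces this is the
#' enclosed volume (mm^3); it negates when either the face winding or the
#' spatial chirality of the mesh flips, which makes it the package's witness
#' for mirror/winding bookkeeping. On open meshes the sum is a pseudo-volume.
#'
#' @param mesh a [triangle_mesh()].
#' @return signed volume in mm^3.
#' @export
signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) return(0)
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  # scalar triple product a . (b x c) per face
  cross <- cbind(b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L],
                 b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L],
                 b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  sum(rowSums(a * cross)) / 6
}

# Per-face areas (mm^2).
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  ab <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  ac <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cross <- cbind(ab[, 2L] * ac[, 3L] - ab[, 3L] * ac[, 2L],
                 ab[, 3L] * ac[, 1L] - ab[, 1L] * ac[, 3L],
                 ab[, 1L] * ac[, 2L] - ab[, 2L] * ac[, 1L])
  0.5 * sqrt(rowSums(cross^2))
}

#' Outward per-vertex normals
#'
#' Area-weighted average of incident face normals, normalised to unit length.
#' Orientation follows the face winding (outward for generator meshes).
#'
#' @param mesh a [triangle_mesh()].
#' @return `n x 3` matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  ab <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  ac <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  fn <- cbind(ab[, 2L] * ac[, 3L] - ab[, 3L] * ac[, 2L],
              ab[, 3L] * ac[, 1L] - ab[, 1L] * ac[, 3L],
              ab[, 1L] * ac[, 2L] - ab[, 2L] * ac[, 1L])
  n <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    idx <- f[, k]
    n[, 1L] <- n[, 1L] + tapply_add(fn[, 1L], idx, nrow(v))
    n[, 2L] <- n[, 2L] + tapply_add(fn[, 2L], idx, nrow(v))
    n[, 3L] <- n[, 3L] + tapply_add(fn[, 3L], idx, nrow(v))
  }
  len <- sqrt(rowSums(n^2))
  len[len < 1e-300] <- 1
  n / len
}

# Sum values into bins given by idx (1..n).
tapply_add <- function(values, idx, n) {
  out <- numeric(n)
  agg <- rowsum(values, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}
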