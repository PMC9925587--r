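#' Estimate the long (proximal-distal) axis of a bone mesh
#'
#' The direction is the dominant principal axis of the vertex covariance. Its
#' sign is chosen so that the wide condylar end is proximal: the 10% of
#' vertices with the largest projection must have a larger perpendicular RMS
#' radius (cross-sectional spread about the axis) than the 10% with the
#' smallest; if not, the direction is flipped. A `proximal_hint` overrides
#' the sign (`direction . hint > 0`).
#'
#' `plateau_level` is the maximum vertex projection onto the final direction,
#' i.e. the level of the tibial plateau.
#'
#' @param mesh a [triangle_mesh()].
#' @param proximal_hint optional 3-vector pointing proximally.
#' @return object of class `axis_estimate` with fields `direction`
#'   (unit 3-vector), `plateau_level` (mm) and `method` (`"pca"`).
#' @export
estimate_axis <- function(mesh, proximal_hint = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  if (nrow(v) < 3L) stop("mesh has fewer than 3 vertices")
  eg <- eigen(stats::cov(v), symmetric = TRUE)
  if (eg$values[2L] <= max(eg$values[1L], 1) * 1e-12)
    stop("degenerate (collinear) vertex set: no axis is defined")
  if (is.null(proximal_hint) &&
      (eg$values[1L] - eg$values[2L]) < 0.01 * eg$values[1L])
    stop(paste("axis is ambiguous (top two covariance eigenvalues within 1%);",
               "pass proximal_hint to pick a direction"))
  dir <- eg$vectors[, 1L]
  if (!is.null(proximal_hint)) {
    h <- as.numeric(proximal_hint)
    if (sum(dir * h) < 0) dir <- -dir
  } else {
    proj <- as.numeric(v %*% dir)
    qs <- stats::quantile(proj, c(0.1, 0.9), names = FALSE)
    ctr <- colMeans(v)
    perp_rms <- function(sel) {
      d <- sweep(v[sel, , drop = FALSE], 2L, ctr)
      along <- as.numeric(d %*% dir)
      sqrt(mean(rowSums(d^2) - along^2))
    }
    if (perp_rms(proj >= qs[2L]) < perp_rms(proj <= qs[1L])) dir <- -dir
  }
  structure(list(direction = dir,
                 plateau_level = max(as.numeric(v %*% dir)),
                 method = "pca"),
            class = "axis_estimate")
}

#' User-supplied anatomical axis
#'
#' @param mesh the mesh whose plateau level should be measured.
#' @param direction 3-vector pointing proximally (normalised internally).
#' @return an `axis_estimate` with `method = "user"`.
#' @export
user_axis <- function(mesh, direction) {
  direction <- as.numeric(direction)
  direction <- direction / sqrt(sum(direction^2))
  structure(list(direction = direction,
                 plateau_level = max(as.numeric(mesh$vertices %*% direction)),
                 method = "user"),
            class = "axis_estimate")
}

#' Crop a mesh to the band below the tibial plateau
#'
#' Retains exactly the faces whose three vertices all project onto the axis
#' at or above `plateau_level - depth`; faces crossing the cut plane are
#' dropped rather than split, leaving an open boundary at the cut (the
#' band-masking option of the correspondence stage exists to discount the
#' resulting cut-edge artifacts). Unreferenced vertices are removed and
#' indices remapped; the attribute `"orig_vertex_index"` maps retained
#' vertices back to the input mesh.
#'
#' @param mesh a [triangle_mesh()].
#' @param axis an `axis_estimate` (typically computed on the fixed/right
#'   surface so both sides are cropped in the same anatomical band).
#' @param depth cut depth below the plateau in mm (default 15).
#' @return the cropped [triangle_mesh()].
#' @export
crop_below_plateau <- function(mesh, axis, depth = 15) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(axis, "axis_estimate"),
            depth > 0)
  proj <- as.numeric(mesh$vertices %*% axis$direction)
  keep_v <- proj >= axis$plateau_level - depth
  fkeep <- keep_v[mesh$faces[, 1L]] & keep_v[mesh$faces[, 2L]] &
    keep_v[mesh$faces[, 3L]]
  if (!any(fkeep))
    stop("crop is empty: the cut plane lies above the whole mesh")
  faces <- mesh$faces[fkeep, , drop = FALSE]
  used <- sort(unique(as.integer(faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  out <- triangle_mesh(mesh$vertices[used, , drop = FALSE],
                       matrix(remap[faces], ncol = 3L),
                       lapply(mesh$fields, function(f) f[used]))
  attr(out, "orig_vertex_index") <- used
  out
}
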