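#' Nearest-point correspondence between two surfaces
#'
#' Matches each source point to the nearest target vertex (`mode = "vertex"`)
#' or to the nearest point on any target triangle (`mode = "surface"`,
#' point-to-triangle projection) and records the Euclidean distances in mm.
#' `"surface"` is the pipeline default for accuracy; `"vertex"` has an exact
#' brute-force oracle and is the testing workhorse. All points start
#' unmasked.
#'
#' @param source_points `n x 3` matrix or a [triangle_mesh()] (its vertices).
#' @param target_mesh a [triangle_mesh()].
#' @param mode `"surface"` or `"vertex"`.
#' @return object of class `correspondence_set` with `source_indices`,
#'   `source_points`, `target_points`, `distances` (mm), `mask` (logical,
#'   `FALSE` = excluded as artifact), `mode` and `target_index` (nearest
#'   vertex or face).
#' @export
nearest_correspondence <- function(source_points, target_mesh,
                                   mode = c("surface", "vertex")) {
  mode <- match.arg(mode)
  if (inherits(source_points, "triangle_mesh"))
    source_points <- source_points$vertices
  src <- as.matrix(source_points)
  stopifnot(inherits(target_mesh, "triangle_mesh"))
  if (nrow(src) == 0L) stop("empty source point set")
  if (n_vertices(target_mesh) == 0L) stop("empty target mesh")
  if (mode == "vertex") {
    nn <- nn_vertex_cpp(src, target_mesh$vertices)
    tgt <- target_mesh$vertices[nn$index, , drop = FALSE]
    tidx <- nn$index
    dist <- nn$distance
  } else {
    if (n_faces(target_mesh) == 0L)
      stop("surface mode needs a target mesh with faces")
    nn <- nn_surface_cpp(src, target_mesh$vertices, target_mesh$faces - 1L)
    tgt <- nn$point
    tidx <- nn$face
    dist <- nn$distance
  }
  structure(list(source_indices = seq_len(nrow(src)),
                 source_points = src,
                 target_points = tgt,
                 distances = as.numeric(dist),
                 mask = rep(TRUE, nrow(src)),
                 mode = mode,
                 target_index = as.integer(tidx)),
            class = "correspondence_set")
}

#' Mask correspondence points near the cut edge
#'
#' Cropping both surfaces a fixed depth below the plateau complicates
#' correspondence around the cut, producing artificially high distances
#' there. This sets `mask = FALSE` for source points whose axis projection
#' lies within `band` mm of the cut level (`plateau_level - depth`), so
#' summaries can be reported masked and unmasked.
#'
#' @param cs a `correspondence_set`.
#' @param axis the `axis_estimate` used for cropping.
#' @param depth the crop depth used (mm).
#' @param band masking band above the cut level (mm, `>= 0`; 0 = no-op).
#' @return the `correspondence_set` with an updated mask.
#' @export
mask_cut_edge <- function(cs, axis, depth = 15, band = 0) {
  stopifnot(inherits(cs, "correspondence_set"), inherits(axis, "axis_estimate"),
            band >= 0)
  if (band == 0) return(cs)
  proj <- as.numeric(cs$source_points %*% axis$direction)
  cut_level <- axis$plateau_level - depth
  cs$mask <- cs$mask & (proj > cut_level + band)
  cs
}

#' Mask correspondence points inside a spherical exclusion region
#'
#' Generic user-supplied exclusion (e.g. around the tibiofibular joint where
#' upstream segmentation is unreliable).
#'
#' @param cs a `correspondence_set`.
#' @param center 3-vector (mm).
#' @param radius sphere radius (mm).
#' @param label region label recorded on the set.
#' @return the `correspondence_set` with an updated mask.
#' @export
mask_sphere_region <- function(cs, center, radius, label = "exclusion") {
  stopifnot(inherits(cs, "correspondence_set"), radius > 0)
  d <- sqrt(rowSums(sweep(cs$source_points, 2L, as.numeric(center))^2))
  cs$mask <- cs$mask & (d > radius)
  regions <- attr(cs, "regions") %||% list()
  regions[[length(regions) + 1L]] <- list(center = as.numeric(center),
                                          radius = radius, label = label)
  attr(cs, "regions") <- regions
  cs
}

distance_stats <- function(d) {
  if (length(d) == 0L) stop("empty distance selection")
  imax <- which.max(d)
  list(n_points = length(d),
       mean_mm = mean(d),
       rms_mm = sqrt(mean(d^2)),
       max_mm = d[imax],
       max_index = imax,
       percentiles = stats::quantile(d, c(0.5, 0.75, 0.95), names = TRUE))
}

#' Per-subject distance summary
#'
#' Summarises correspondence distances: point count, mean, RMS (square root
#' of the mean of squared distances), maximum with its source index, and the
#' 50/75/95th percentiles — always in both raw and masked variants. The mean
#' and RMS are reported separately and explicitly (the RMS is the quantity
#' conventionally quoted for surface superimposition residuals).
#'
#' @param cs a `correspondence_set`.
#' @param use_mask whether the top-level statistics come from the masked
#'   selection (raw and masked variants are both retained either way).
#' @return object of class `symmetry_summary` with `raw`, `masked` and the
#'   primary statistics promoted to the top level.
#' @export
subject_summary <- function(cs, use_mask = FALSE) {
  stopifnot(inherits(cs, "correspondence_set"))
  raw <- distance_stats(cs$distances)
  masked <- if (any(cs$mask)) {
    st <- distance_stats(cs$distances[cs$mask])
    st$max_index <- which(cs$mask)[st$max_index]
    st
  } else NULL
  if (use_mask && is.null(masked))
    stop("all points are masked: masked summary is undefined")
  primary <- if (use_mask) masked else raw
  structure(c(primary,
              list(raw = raw, masked = masked, use_mask = use_mask,
                   n_masked_out = sum(!cs$mask))),
            class = "symmetry_summary")
}

#' Attach distances to a mesh as a heatmap field
#'
#' Populates the scalar field `"distance_mm"` on the source mesh (one
#' distance per vertex) together with a companion `"mask"` field (1 = kept,
#' 0 = excluded as artifact), ready for PLY export and display in any mesh
#' viewer.
#'
#' @param source_mesh the mesh whose vertices were the correspondence source.
#' @param cs the matching `correspondence_set`.
#' @return the mesh with `distance_mm` and `mask` fields.
#' @export
heatmap_field <- function(source_mesh, cs) {
  stopifnot(inherits(source_mesh, "triangle_mesh"),
            inherits(cs, "correspondence_set"))
  if (length(cs$distances) != n_vertices(source_mesh))
    stop("correspondence set does not provide one distance per source vertex")
  source_mesh$fields[["distance_mm"]] <- cs$distances
  source_mesh$fields[["mask"]] <- as.numeric(cs$mask)
  source_mesh
}

#' Symmetric Hausdorff distance between two meshes (vertex mode)
#'
#' Diagnostic: the maximum over both directed maxima of nearest-vertex
#' distances. Every directed mean correspondence distance is bounded above
#' by this quantity.
#'
#' @param mesh_a,mesh_b [triangle_mesh()] objects.
#' @return distance in mm.
#' @export
hausdorff_vertex <- function(mesh_a, mesh_b) {
  ab <- nn_vertex_cpp(mesh_a$vertices, mesh_b$vertices)$distance
  ba <- nn_vertex_cpp(mesh_b$vertices, mesh_a$vertices)$distance
  max(max(ab), max(ba))
}
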