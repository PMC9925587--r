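#' Rigid transform (proper rotation + translation)
#'
#' Registration output: `p -> R p + t` with `R` orthonormal and
#' `det(R) = +1`. A chirality change is always the mirroring step's job and
#' never the registration's, so improper rotations are rejected here.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation 3-vector (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal (R'R != I)")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be proper (det = +1); reflections are not rigid transforms here")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("rigid_transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1L], x$translation[2L], x$translation[3L]))
  invisible(x)
}

#' Apply a rigid transform (optionally scaled)
#'
#' Maps each point `p` to `scale * R p + t`. For meshes, faces and scalar
#' fields are untouched.
#'
#' @param x a point matrix (`n x 3`) or a [triangle_mesh()].
#' @param transform a [rigid_transform()].
#' @param scale similarity scale factor (1 for rigid).
#' @return object of the same kind as `x`.
#' @export
apply_transform <- function(x, transform, scale = 1) {
  stopifnot(inherits(transform, "rigid_transform"), scale > 0)
  if (inherits(x, "triangle_mesh")) {
    m <- x
    m$vertices <- apply_transform(x$vertices, transform, scale)
    return(m)
  }
  pts <- as.matrix(x)
  sweep(scale * (pts %*% t(transform$rotation)), 2L, transform$translation, "+")
}

#' Compose and invert rigid transforms
#'
#' `compose_transform(a, b)` is "apply `b` first, then `a`".
#'
#' @param a,b,transform [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transform
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, as.numeric(-rt %*% transform$translation))
}

#' Rotation matrix about an axis
#'
#' Rodrigues' formula.
#'
#' @param axis nonzero 3-vector.
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
axis_angle_rotation <- function(axis, angle) {
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, axis[3L], -axis[2L],
                -axis[3L], 0, axis[1L],
                axis[2L], -axis[1L], 0), 3L, 3L)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

#' Random rigid transform
#'
#' Rotation about a uniformly random axis by an angle uniform in
#' `[0, max_angle_deg]`, translation uniform in a cube of half-width
#' `max_translation_mm`.
#'
#' @param max_angle_deg maximum rotation angle (degrees).
#' @param max_translation_mm maximum per-axis translation (mm).
#' @param seed integer seed.
#' @return a [rigid_transform()].
#' @export
random_rigid_transform <- function(max_angle_deg, max_translation_mm, seed) {
  with_seed(seed, {
    ax <- rnorm(3L)
    ang <- runif(1L, 0, max_angle_deg) * pi / 180
    tr <- runif(3L, -max_translation_mm, max_translation_mm)
    rigid_transform(axis_angle_rotation(ax, ang), tr)
  })
}

rotation_angle_deg <- function(R) {
  cosang <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, cosang))) * 180 / pi
}
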