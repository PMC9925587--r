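#' CPD registration settings
#'
#' Parameters of the rigid Coherent Point Drift fit. The defaults are chosen
#' for robustness at desk scale: a mild uniform outlier weight `w = 0.1`
#' absorbs segmentation debris (e.g. around the tibiofibular junction),
#' `tolerance` is the relative change of the negative log-likelihood at which
#' iteration stops, and `subsample_n` caps the per-surface point count fed to
#' the O(M*N) EM iteration (`"all"` disables subsampling; meshes at or below
#' the cap are used as-is).
#'
#' @param w uniform outlier weight in `[0, 1)`.
#' @param max_iterations positive integer.
#' @param tolerance positive relative objective-change threshold.
#' @param allow_scaling fit a similarity scale as well (default off: a scale
#'   fit could mask true size asymmetry between two bones of one subject).
#' @param subsample_n positive integer or `"all"`.
#' @param seed integer seed used when subsampling.
#' @return object of class `cpd_config`.
#' @export
cpd_config <- function(w = 0.1, max_iterations = 150L, tolerance = 1e-8,
                       allow_scaling = FALSE, subsample_n = 2000L, seed = 1L) {
  stopifnot(is.numeric(w), length(w) == 1L, w >= 0, w < 1,
            tolerance > 0, max_iterations >= 1)
  if (!identical(subsample_n, "all")) {
    subsample_n <- as.integer(subsample_n)
    stopifnot(subsample_n >= 4L)
  }
  structure(list(w = w, max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, allow_scaling = isTRUE(allow_scaling),
                 subsample_n = subsample_n, seed = as.integer(seed)),
            class = "cpd_config")
}

#' Area-weighted surface subsampling
#'
#' Draws `n` points uniformly by surface area over the triangles of a mesh
#' (triangles chosen with probability proportional to area, then uniform
#' barycentric coordinates), reproducibly for a fixed seed. This samples the
#' surface, not the vertex set.
#'
#' @param mesh a [triangle_mesh()].
#' @param n number of points (`>= 4`).
#' @param seed integer seed.
#' @return `n x 3` matrix of surface points (mm), with attribute
#'   `"triangle"` giving the source face of each point.
#' @export
subsample_points <- function(mesh, n, seed = 1L) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (n < 4L) stop("subsample size must be at least 4 points")
  areas <- face_areas(mesh)
  with_seed(seed, {
    tri <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = areas)
    r1 <- sqrt(runif(n))
    r2 <- runif(n)
    a <- mesh$vertices[mesh$faces[tri, 1L], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[tri, 2L], , drop = FALSE]
    c_ <- mesh$vertices[mesh$faces[tri, 3L], , drop = FALSE]
    pts <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c_
    attr(pts, "triangle") <- tri
    pts
  })
}

#' Rigid Coherent Point Drift registration
#'
#' Fits the rigid transform (optionally with a similarity scale) that
#' superimposes `source` onto `target`. The source points are treated as
#' centroids of an isotropic Gaussian mixture with shared variance `sigma2`,
#' plus a uniform outlier component of weight `w`; EM alternates posterior
#' correspondence probabilities (E-step) with a closed-form update of the
#' rotation (SVD of the posterior-weighted cross-covariance, projected to
#' `det = +1`), translation and `sigma2` (M-step), until the relative change
#' of the negative log-likelihood drops below `tolerance`. `sigma2` is
#' initialised from the mean squared distance between the two sets.
#'
#' The rotation is always proper: registration never absorbs a reflection.
#'
#' @param source `M x 3` moving point matrix (mm).
#' @param target `N x 3` fixed point matrix (mm).
#' @param config a [cpd_config()].
#' @return object of class `registration_result` with elements `transform`
#'   (a [rigid_transform()]), `scale`, `sigma2` (final variance, mm^2),
#'   `iterations`, `converged`, and `objective_trace` (negative
#'   log-likelihood per iteration, non-increasing).
#' @export
cpd_rigid <- function(source, target, config = cpd_config()) {
  Y <- as.matrix(source)
  X <- as.matrix(target)
  if (nrow(Y) < 4L || nrow(X) < 4L)
    stop("CPD needs at least 4 points in each set")
  stopifnot(ncol(Y) == 3L, ncol(X) == 3L, inherits(config, "cpd_config"))
  N <- nrow(X); M <- nrow(Y); D <- 3L

  # sigma2 init: mean squared pairwise distance between the two sets
  sx <- colSums(X); sy <- colSums(Y)
  sigma2 <- (M * sum(X^2) + N * sum(Y^2) - 2 * sum(sx * sy)) / (D * N * M)
  sigma2 <- max(sigma2, 1e-12)

  R <- diag(3); t_ <- c(0, 0, 0); s <- 1
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  L_prev <- NA_real_
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    TY <- sweep(s * (Y %*% t(R)), 2L, t_, "+")
    es <- cpd_estep_cpp(X, TY, sigma2, config$w)
    trace <- c(trace, es$L)
    Np <- sum(es$P1)
    if (Np < .Machine$double.eps) {
      warning("CPD: all points classified as outliers; returning current transform")
      break
    }
    mu_x <- as.numeric(crossprod(X, es$Pt1)) / Np
    mu_y <- as.numeric(crossprod(Y, es$P1)) / Np
    A <- crossprod(es$PX, Y) - Np * tcrossprod(mu_x, mu_y)
    sv <- svd(A)
    C <- diag(c(1, 1, det(sv$u %*% t(sv$v))))
    R <- sv$u %*% C %*% t(sv$v)
    xx <- sum(es$Pt1 * rowSums(sweep(X, 2L, mu_x)^2))
    yy <- sum(es$P1 * rowSums(sweep(Y, 2L, mu_y)^2))
    trSC <- sum(diag(C) * sv$d)
    if (config$allow_scaling) {
      s <- trSC / yy
      sigma2_new <- (xx - s * trSC) / (Np * D)
    } else {
      s <- 1
      sigma2_new <- (xx + yy - 2 * trSC) / (Np * D)
    }
    t_ <- mu_x - s * as.numeric(R %*% mu_y)
    if (!is.finite(sigma2_new) || sigma2_new < 1e-12) {
      # variance collapse: the fit is (numerically) exact
      sigma2 <- 1e-12
      converged <- TRUE
      break
    }
    sigma2 <- sigma2_new
    if (!is.na(L_prev)) {
      rel <- abs(L_prev - es$L) / max(abs(L_prev), .Machine$double.eps)
      if (rel < config$tolerance) {
        converged <- TRUE
        break
      }
    }
    L_prev <- es$L
  }
  if (!converged)
    warning(sprintf("CPD did not converge within %d iterations", config$max_iterations))
  structure(list(transform = rigid_transform(R, t_), scale = s,
                 sigma2 = sigma2, iterations = iter, converged = converged,
                 objective_trace = trace),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: %d iterations (%s), sigma2 = %.3g mm^2, scale = %.4f\n",
              x$iterations, if (x$converged) "converged" else "not converged",
              x$sigma2, x$scale))
  print(x$transform)
  invisible(x)
}

#' Moment-based rigid pre-alignment
#'
#' CPD's EM iteration is a local optimiser, so the pipeline seeds it with a
#' coarse global alignment: centroids and principal axes of both clouds are
#' matched, the four proper sign assignments of the axes are tried, and the
#' candidate with the smallest mean nearest-neighbour distance wins. This
#' makes the pipeline invariant to arbitrarily large rigid misalignment
#' (e.g. the rotation introduced by the choice of mirror plane).
#'
#' @param source,target point matrices (`n x 3`).
#' @return a [rigid_transform()] mapping `source` near `target`.
#' @export
prealign_pca <- function(source, target) {
  Y <- as.matrix(source); X <- as.matrix(target)
  cy <- colMeans(Y); cx <- colMeans(X)
  vy <- eigen(stats::cov(Y), symmetric = TRUE)$vectors
  vx <- eigen(stats::cov(X), symmetric = TRUE)$vectors
  if (det(vy) < 0) vy[, 3L] <- -vy[, 3L]
  if (det(vx) < 0) vx[, 3L] <- -vx[, 3L]
  flips <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  best <- NULL
  best_cost <- Inf
  for (fl in flips) {
    R <- vx %*% diag(fl) %*% t(vy)
    tr <- cx - as.numeric(R %*% cy)
    tf <- rigid_transform(R, tr)
    moved <- apply_transform(Y, tf)
    cost <- mean(nn_vertex_cpp(moved, X)$distance)
    if (cost < best_cost) {
      best_cost <- cost
      best <- tf
    }
  }
  best
}
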