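#' Default run configuration
#'
#' One nested list drives the whole per-subject workflow; every report echoes
#' the effective configuration so a run is reproducible from its own output.
#'
#' Blocks: `mirror_side` (which side is mirrored onto the other; the
#' convention is to mirror the left), `mirror_plane` (optional user-supplied
#' [plane()] overriding the covariance-based default), `registration` (CPD
#' settings, see
#' [cpd_config()], plus `prealign` for the moment-based global seed and
#' `second_pass` for the re-registration of the cropped surfaces),
#' `crop` (`depth_mm` below the plateau, optional user `axis` direction),
#' `correspondence` (`mode`, cut-edge `mask_band_mm`, optional spherical
#' `exclusion` regions), and a master `seed`.
#'
#' @param ... named overrides merged (recursively) over the defaults, e.g.
#'   `run_config(crop = list(depth_mm = 10))`.
#' @return a nested configuration list of class `run_config`.
#' @export
run_config <- function(...) {
  base <- list(
    mirror_side = "left",
    mirror_plane = NULL,
    registration = list(w = 0.1, tolerance = 1e-8, max_iterations = 150L,
                        subsample_n = 2000L, allow_scaling = FALSE,
                        prealign = TRUE, second_pass = TRUE),
    crop = list(depth_mm = 15, axis = NULL),
    correspondence = list(mode = "surface", mask_band_mm = 0,
                          exclusion = NULL),
    seed = 1L,
    log_level = "info")
  cfg <- merge_config(base, list(...))
  stopifnot(cfg$crop$depth_mm > 0, cfg$mirror_side %in% c("left", "right"))
  class(cfg) <- "run_config"
  cfg
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML run configuration
#'
#' Keys mirror [run_config()]; unknown keys are rejected at validation.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  do.call(run_config, yaml::read_yaml(path))
}

reg_points <- function(mesh, cfg, seed) {
  n <- cfg$registration$subsample_n
  if (identical(n, "all") || n_vertices(mesh) <= n) mesh$vertices
  else subsample_points(mesh, n, seed = seed)
}

stage_eval <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full per-subject symmetry workflow
#'
#' Executes, in order: (1) mirror the configured side across the sagittal
#' plane; (2) rigid CPD superimposition of the mirrored surface onto the
#' contralateral surface (seeded by a moment-based pre-alignment);
#' (3) long-axis and plateau-level estimation on the fixed surface;
#' (4) cropping of both surfaces to the band `depth_mm` below the plateau,
#' using that one shared axis and level; (5) a second CPD pass on the
#' cropped surfaces, so alignment of the proximal region is not dragged by
#' distal points outside the region of interest; (6) nearest-point
#' correspondence from the moving cropped surface to the fixed cropped
#' surface; (7) optional cut-edge/exclusion masking; (8) distance summary
#' and heatmap field.
#'
#' @param left,right [triangle_mesh()] surfaces of the left and right bone
#'   (mm).
#' @param config a [run_config()].
#' @param subject_id label recorded in the report.
#' @return object of class `subject_symmetry_report`; key fields:
#'   `mean_mm`, `rms_mm`, `max_mm` (satisfying mean <= RMS <= max),
#'   `percentiles`, `raw`/`masked` summary variants, `reverse_mean_mm`
#'   (fixed-to-moving diagnostic), `transforms` for both passes, `heatmap`
#'   (the cropped moving mesh carrying `distance_mm`), `max_vertex_input`
#'   (index of the maximum-distance vertex in the input moving mesh), the
#'   estimated `axis` and mirror `plane`, `config` echo and `warnings`.
#' @export
run_subject <- function(left, right, config = run_config(),
                        subject_id = "subject") {
  stopifnot(inherits(left, "triangle_mesh"), inherits(right, "triangle_mesh"),
            inherits(config, "run_config"))
  warn <- character(0)
  note <- function(...) warn <<- c(warn, sprintf(...))

  if (config$mirror_side == "left") {
    moving <- left; fixed <- right
  } else {
    moving <- right; fixed <- left
  }

  ## (1) mirror (any plane choice differs from any other by a rigid motion
  ## that registration absorbs; only the chirality flip matters)
  pl <- stage_eval("mirror",
                   config$mirror_plane %||% default_sagittal_plane(moving))
  mirrored <- stage_eval("mirror", mirror_across_plane(moving, pl))

  rc <- config$registration
  ccfg <- cpd_config(w = rc$w, max_iterations = rc$max_iterations,
                     tolerance = rc$tolerance,
                     allow_scaling = rc$allow_scaling,
                     subsample_n = rc$subsample_n, seed = config$seed)

  ## (2) first superimposition on the full surfaces
  pass1 <- stage_eval("register_full", {
    src <- reg_points(mirrored, config, stage_seed(config$seed, "subsample1"))
    tgt <- reg_points(fixed, config, stage_seed(config$seed, "subsample1") + 1L)
    pre <- if (isTRUE(rc$prealign)) prealign_pca(src, tgt)
           else rigid_transform()
    fit <- cpd_rigid(apply_transform(src, pre), tgt, ccfg)
    if (!fit$converged) note("first registration pass did not converge")
    list(transform = compose_transform(fit$transform, pre), fit = fit)
  })
  moving_aln <- apply_transform(mirrored, pass1$transform, pass1$fit$scale)

  ## (3) axis + plateau level on the fixed surface
  axis <- stage_eval("axis", {
    if (!is.null(config$crop$axis)) user_axis(fixed, config$crop$axis)
    else estimate_axis(fixed)
  })

  ## (4) crop both with the same axis and level
  depth <- config$crop$depth_mm
  crop_f <- stage_eval("crop", crop_below_plateau(fixed, axis, depth))
  crop_m <- stage_eval("crop", crop_below_plateau(moving_aln, axis, depth))

  ## (5) second pass on the crops
  pass2 <- if (isTRUE(rc$second_pass)) {
    stage_eval("register_crop", {
      src <- reg_points(crop_m, config, stage_seed(config$seed, "subsample2"))
      tgt <- reg_points(crop_f, config, stage_seed(config$seed, "subsample2") + 1L)
      fit <- cpd_rigid(src, tgt, ccfg)
      if (!fit$converged) note("second registration pass did not converge")
      list(transform = fit$transform, fit = fit)
    })
  } else {
    list(transform = rigid_transform(), fit = NULL)
  }
  crop_m <- apply_transform(crop_m, pass2$transform,
                            if (is.null(pass2$fit)) 1 else pass2$fit$scale)

  ## (6) correspondence, moving -> fixed
  cs <- stage_eval("correspondence",
                   nearest_correspondence(crop_m, crop_f,
                                          mode = config$correspondence$mode))

  ## (7) masking
  band <- config$correspondence$mask_band_mm
  if (band > 0) cs <- stage_eval("mask", mask_cut_edge(cs, axis, depth, band))
  for (ex in config$correspondence$exclusion %||% list())
    cs <- stage_eval("mask", mask_sphere_region(cs, ex$center, ex$radius,
                                                ex$label %||% "exclusion"))

  ## (8) summary + heatmap
  use_mask <- band > 0 || length(config$correspondence$exclusion %||% list()) > 0
  summ <- stage_eval("summary", subject_summary(cs, use_mask = use_mask))
  heat <- stage_eval("summary", heatmap_field(crop_m, cs))
  rev_cs <- stage_eval("summary",
                       nearest_correspondence(crop_f, crop_m,
                                              mode = config$correspondence$mode))

  orig_idx <- attr(crop_m, "orig_vertex_index")
  max_vertex_input <- if (!is.null(orig_idx)) orig_idx[summ$max_index] else NA_integer_
  report <- structure(list(
    subject_id = subject_id,
    n_points = summ$n_points,
    mean_mm = summ$mean_mm,
    rms_mm = summ$rms_mm,
    max_mm = summ$max_mm,
    max_location = as.numeric(cs$source_points[summ$max_index, ]),
    max_vertex_input = max_vertex_input,
    percentiles = summ$percentiles,
    raw = summ$raw,
    masked = summ$masked,
    reverse_mean_mm = mean(rev_cs$distances),
    transforms = list(pass1 = pass1$transform, pass2 = pass2$transform),
    mirror_plane = pl,
    axis = axis,
    heatmap = heat,
    config = config,
    version = as.character(packageVersion("bisym")),
    warnings = warn),
    class = "subject_symmetry_report")
  stopifnot(report$mean_mm <= report$rms_mm + 1e-12,
            report$rms_mm <= report$max_mm + 1e-12)
  report
}

#' @export
print.subject_symmetry_report <- function(x, ...) {
  cat(sprintf("subject_symmetry_report '%s': n = %d correspondence points\n",
              x$subject_id, x$n_points))
  cat(sprintf("  mean %.4f mm | RMS %.4f mm | max %.4f mm\n",
              x$mean_mm, x$rms_mm, x$max_mm))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Serialise a subject report to JSON
#'
#' The heatmap mesh is written separately (see [write_mesh()]); the JSON
#' carries statistics, transforms, configuration echo and warnings.
#'
#' @param report a `subject_symmetry_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_subject_report <- function(report, path) {
  out <- report[c("subject_id", "n_points", "mean_mm", "rms_mm", "max_mm",
                  "max_location", "max_vertex_input", "reverse_mean_mm",
                  "version", "warnings")]
  out$percentiles <- as.list(report$percentiles)
  out$raw <- report$raw
  out$raw$percentiles <- as.list(report$raw$percentiles)
  if (!is.null(report$masked)) {
    out$masked <- report$masked
    out$masked$percentiles <- as.list(report$masked$percentiles)
  }
  out$transforms <- lapply(report$transforms, function(tf)
    list(rotation = tf$rotation, translation = tf$translation))
  out$axis <- list(direction = report$axis$direction,
                   plateau_level = report$axis$plateau_level,
                   method = report$axis$method)
  out$mirror_plane <- list(point = report$mirror_plane$point,
                           normal = report$mirror_plane$normal)
  out$config <- unclass_config(report$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, null = "null")
  invisible(path)
}

unclass_config <- function(cfg) {
  cfg <- unclass(cfg)
  rapply(cfg, function(x) x, how = "replace")
}

#' Aggregate per-subject mean distances into cohort statistics
#'
#' @param means numeric vector of per-subject mean distances (mm).
#' @return list with `n`, `mean_mm`, `sd_mm` (sample SD; `NA` for a single
#'   subject rather than 0) and `sem_mm`.
#' @export
cohort_aggregate <- function(means) {
  n <- length(means)
  stopifnot(n >= 1)
  sdv <- if (n > 1L) stats::sd(means) else NA_real_
  list(n = n, mean_mm = mean(means), sd_mm = sdv,
       sem_mm = if (n > 1L) sdv / sqrt(n) else NA_real_)
}

#' Tukey boxplot statistics of pooled distances
#'
#' Quartiles by linear interpolation (type 7), whiskers at the most extreme
#' values within 1.5 IQR of the quartiles, remaining points counted as
#' outliers. The convention is recorded in the output because boxplot
#' conventions vary between tools.
#'
#' @param d numeric vector of distances (mm).
#' @return data frame with columns `stat`, `value`.
#' @export
boxplot_stats <- function(d) {
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3L] - q[1L]
  lo <- min(d[d >= q[1L] - 1.5 * iqr])
  hi <- max(d[d <= q[3L] + 1.5 * iqr])
  data.frame(
    stat = c("n", "median", "q1", "q3", "whisker_low", "whisker_high",
             "n_outliers", "whisker_rule"),
    value = c(length(d), q[2L], q[1L], q[3L],
              lo, hi, sum(d < lo | d > hi), 1.5),
    stringsAsFactors = FALSE)
}

#' Run the workflow over a cohort manifest
#'
#' Runs [run_subject()] for every row of the manifest. A failing subject is
#' logged, reported in the `failures` element and skipped — a cohort run is
#' never destroyed by one bad mesh — but failures are never silent: they are
#' returned, and written reports flag partial success.
#'
#' @param manifest data frame with columns `subject_id`, `left_path`,
#'   `right_path`, or a path to such a CSV.
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, writes one JSON
#'   report and heatmap PLY per subject, `cohort.json` and `boxplot.csv`.
#' @return object of class `cohort_summary`: `subjects` (list of reports),
#'   `aggregate` (mean/SD/SEM of per-subject means), `boxplot` (pooled
#'   Tukey statistics), `failures` (named character vector of error
#'   messages), `config`.
#' @export
run_cohort <- function(manifest, config = run_config(), out_dir = NULL) {
  if (is.character(manifest)) manifest <- read.csv(manifest,
                                                   stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "left_path", "right_path") %in%
                  colnames(manifest)))
  if (nrow(manifest) < 1L) stop("cohort manifest is empty")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  reports <- list()
  failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    res <- tryCatch({
      l <- read_mesh(manifest$left_path[i])
      r <- read_mesh(manifest$right_path[i])
      run_subject(l, r, config, subject_id = sid)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[sid] <- conditionMessage(res)
      message(sprintf("cohort: subject %s failed and was skipped: %s", sid,
                      conditionMessage(res)))
    } else {
      reports[[sid]] <- res
      if (!is.null(out_dir)) {
        write_subject_report(res, file.path(out_dir, paste0(sid, "_report.json")))
        write_mesh(res$heatmap, file.path(out_dir, paste0(sid, "_heatmap.ply")))
      }
    }
  }
  if (!length(reports)) stop("cohort: every subject failed")
  means <- vapply(reports, `[[`, 0, "mean_mm")
  pooled <- unlist(lapply(reports, function(r) r$heatmap$fields$distance_mm),
                   use.names = FALSE)
  agg <- cohort_aggregate(means)
  box <- boxplot_stats(pooled)
  out <- structure(list(subjects = reports, aggregate = agg, boxplot = box,
                        failures = failures, config = config,
                        version = as.character(packageVersion("bisym"))),
                   class = "cohort_summary")
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(n_subjects = agg$n, mean_mm = agg$mean_mm, sd_mm = agg$sd_mm,
           sem_mm = agg$sem_mm,
           subject_means_mm = as.list(means),
           failures = as.list(failures),
           version = out$version,
           config = unclass_config(config)),
      file.path(out_dir, "cohort.json"), auto_unbox = TRUE, digits = 10,
      pretty = TRUE, null = "null")
    write.csv(box, file.path(out_dir, "boxplot.csv"), row.names = FALSE)
  }
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("cohort_summary: %d subjects, mean of means %.4f mm (SD %s, SEM %s)\n",
              a$n, a$mean_mm,
              if (is.na(a$sd_mm)) "n/a" else sprintf("%.4f", a$sd_mm),
              if (is.na(a$sem_mm)) "n/a" else sprintf("%.4f", a$sem_mm)))
  if (length(x$failures))
    cat(sprintf("  %d subject(s) failed: %s\n", length(x$failures),
                paste(names(x$failures), collapse = ", ")))
  invisible(x)
}
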