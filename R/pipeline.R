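#' Full treeline-ecotone pattern analysis
#'
#' Runs the complete pipeline on a tree point pattern: belt/subplot
#' gridding, canopy-height belt vectors, the four abruptness metrics,
#' union-of-crowns cover rasterization, the logistic discreteness fit,
#' and threshold classification of both axes.
#'
#' @param trees a `tree_records` data frame (see [read_point_pattern()]
#'   / [as_tree_records()]).
#' @param spec a [transect_spec()].
#' @param config an [ecotone_config()].
#' @param krummholz_present logical, or `NULL` to infer from the
#'   records' `growth_form` flags (present iff any record is flagged
#'   krummholz).
#' @param cover_grid optional `cover_grid` (e.g. from
#'   [read_cover_grid()]); if supplied, crown rasterization is skipped
#'   and discreteness is computed from it.
#' @param shift_scan if TRUE, also run [belt_shift_scan()].
#' @return An object of class `treeline_report`: abruptness result and
#'   class, discreteness result and class, belt-wise diagnostics, the
#'   thresholds used, the load report if present, and optionally the
#'   shift scan.
#' @export
treeline_metrics <- function(trees, spec, config = ecotone_config(),
                             krummholz_present = NULL,
                             cover_grid = NULL, shift_scan = FALSE) {
  stopifnot(inherits(spec, "transect_spec"),
            inherits(config, "ecotone_config"))
  if (is.null(krummholz_present))
    krummholz_present <- "krummholz" %in% trees$growth_form

  gridded <- grid_trees(trees, spec)
  stats <- subplot_canopy_heights(gridded, spec)
  vectors <- belt_max_vectors(stats, spec)
  abrupt <- abruptness_metrics(vectors$Max_H, vectors$Max2_H, spec)
  abrupt_class <- classify_abruptness(abrupt, krummholz_present,
                                      config$thresholds)

  if (is.null(cover_grid))
    cover_grid <- rasterize_cover(trees, spec, config$supersample)
  cover_points <- subplot_mean_cover(cover_grid, spec)
  discrete <- fit_cover_logistic(cover_points, spec$length,
                                 config$thresholds)
  discrete_class <- classify_discreteness(discrete, config$thresholds)

  belt_cover <- vapply(split(cover_points$cover,
                             cover_points$belt_index), mean, numeric(1))
  report <- list(
    spec = spec, thresholds = config$thresholds,
    crown_ratio = config$crown_ratio, supersample = config$supersample,
    krummholz_present = krummholz_present,
    abruptness = abrupt, abruptness_class = abrupt_class,
    discreteness = discrete, discreteness_class = discrete_class,
    belt_counts = vectors$n_individuals,
    belt_cover_mean = as.numeric(belt_cover),
    cover_points = cover_points,
    load_report = attr(trees, "load_report"),
    warnings = c(abrupt$warnings,
                 if (length(abrupt_class$boundary))
                   paste("abruptness metric exactly on a threshold:",
                         paste(abrupt_class$boundary, collapse = ", ")),
                 if (isTRUE(discrete_class$boundary))
                   "fitted s exactly on the discreteness threshold",
                 if (abrupt_class$consensus == "conflicting")
                   "abruptness metrics conflict; assign the site manually"))
  if (isTRUE(shift_scan))
    report$shift_scan <- belt_shift_scan(trees, spec)
  class(report) <- "treeline_report"
  report
}

#' @export
print.treeline_report <- function(x, ...) {
  cat("== Treeline ecotone pattern report ==\n")
  print(x$spec)
  print(x$abruptness)
  print(x$abruptness_class)
  print(x$discreteness)
  print(x$discreteness_class)
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}
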