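#' Transect geometry and grid resolutions
#'
#' Defines the rectangular hillslope transect and the grids used to
#' aggregate individual-tree point patterns: elevational belts (strips
#' perpendicular to the slope), square subplots within belts, and the
#' fine cell grid used for cover rasterization. Elevation increases
#' along the y axis; y = 0 is the transect bottom.
#'
#' @param length transect extent along the elevational gradient (m).
#' @param width across-slope extent (m).
#' @param belt_width elevational belt width (m). Belt 1 is the lowest.
#' @param subplot_size subplot edge length (m).
#' @param cell_size cover raster cell edge (m); must divide
#'   `subplot_size`.
#' @param seedling_cutoff minimum height (m) for an individual to enter
#'   canopy-height and density statistics (strictly greater than).
#' @param forest_cutoff canopy-height truncation threshold (m); the
#'   truncation belt is the topmost belt whose maximum canopy height
#'   exceeds this value.
#'
#' @return An object of class `transect_spec` with derived fields
#'   `n_belts`, `subplots_per_belt` and `belt_midpoints` (y coordinate
#'   of each belt centre, bottom to top).
#' @examples
#' spec <- transect_spec(length = 180, width = 60)
#' spec$n_belts            # 36
#' spec$subplots_per_belt  # 12
#' @export
transect_spec <- function(length, width, belt_width = 5, subplot_size = 5,
                          cell_size = 1, seedling_cutoff = 0.5,
                          forest_cutoff = 3) {
  stopifnot(length > 0, width > 0, belt_width > 0, subplot_size > 0,
            cell_size > 0, seedling_cutoff >= 0, forest_cutoff > 0)
  n_belts <- length / belt_width
  subplots_per_belt <- width / subplot_size
  if (!is_whole(n_belts) || n_belts < 1)
    stop("transect length (", length, " m) is not a positive integer ",
         "multiple of belt_width (", belt_width, " m)", call. = FALSE)
  if (!is_whole(subplots_per_belt) || subplots_per_belt < 1)
    stop("transect width (", width, " m) is not a positive integer ",
         "multiple of subplot_size (", subplot_size, " m)", call. = FALSE)
  if (!is_whole(subplot_size / cell_size))
    stop("cell_size (", cell_size, " m) must divide subplot_size (",
         subplot_size, " m)", call. = FALSE)
  n_belts <- as.integer(round(n_belts))
  subplots_per_belt <- as.integer(round(subplots_per_belt))
  structure(
    list(length = length, width = width, belt_width = belt_width,
         subplot_size = subplot_size, cell_size = cell_size,
         seedling_cutoff = seedling_cutoff, forest_cutoff = forest_cutoff,
         n_belts = n_belts, subplots_per_belt = subplots_per_belt,
         belt_midpoints = (seq_len(n_belts) - 0.5) * belt_width),
    class = "transect_spec")
}

#' @export
print.transect_spec <- function(x, ...) {
  cat("Transect: ", x$length, " m (uphill) x ", x$width, " m\n", sep = "")
  cat("  ", x$n_belts, " belts of ", x$belt_width, " m; ",
      x$subplots_per_belt, " subplots of ", x$subplot_size,
      " m per belt; ", x$cell_size, "-m cover cells\n", sep = "")
  cat("  seedling cutoff > ", x$seedling_cutoff, " m; forest cutoff ",
      x$forest_cutoff, " m\n", sep = "")
  invisible(x)
}

#' Classification thresholds for treeline forms
#'
#' The threshold conventions used to map metric values to categorical
#' treeline forms. Absolute abruptness cuts are in metres of canopy
#' height lost between successive belts; normalised cuts are
#' dimensionless fractions of the transect's maximum canopy height.
#' When a krummholz belt is present the absolute cuts are reduced by
#' `krummholz_reduction_m` (stunted growth forms compress the height
#' scale of the transition). The steepness cut `s_discrete` separates
#' discrete from diffuse cover transitions; `c_max_min` is the minimum
#' fitted forest cover for discreteness to be meaningful, and
#' `y_l_margin_m` the distance from the transect bottom below which a
#' fitted transition midpoint cannot be interpreted.
#'
#' @param n_abr_gradual,n_abr_abrupt cuts on the normalised abruptness
#'   metrics (gradual below the first, abrupt above the second).
#' @param a_abr_gradual_m,a_abr_abrupt_m cuts on absolute abruptness (m).
#' @param a_abr2_gradual_m gradual cut for the second-maximum absolute
#'   metric (m); its abrupt cut is shared with `a_abr_abrupt_m`.
#' @param krummholz_reduction_m reduction (m) applied to all absolute
#'   cuts when krummholz is present.
#' @param s_discrete minimum fitted logistic steepness (per m) for a
#'   discrete forest edge.
#' @param c_max_min minimum fitted forest cover for a discrete label.
#' @param y_l_margin_m margin (m) above the transect bottom within which
#'   a fitted midpoint invalidates the fit.
#' @return An object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(n_abr_gradual = 0.25,
                                      n_abr_abrupt = 0.40,
                                      a_abr_gradual_m = 2.0,
                                      a_abr_abrupt_m = 3.0,
                                      a_abr2_gradual_m = 1.5,
                                      krummholz_reduction_m = 1.0,
                                      s_discrete = 0.2,
                                      c_max_min = 0.4,
                                      y_l_margin_m = 5.0) {
  th <- list(n_abr_gradual = n_abr_gradual, n_abr_abrupt = n_abr_abrupt,
             a_abr_gradual_m = a_abr_gradual_m,
             a_abr_abrupt_m = a_abr_abrupt_m,
             a_abr2_gradual_m = a_abr2_gradual_m,
             krummholz_reduction_m = krummholz_reduction_m,
             s_discrete = s_discrete, c_max_min = c_max_min,
             y_l_margin_m = y_l_margin_m)
  if (any(unlist(th) <= 0))
    stop("all classification thresholds must be positive", call. = FALSE)
  if (n_abr_gradual >= n_abr_abrupt || a_abr_gradual_m >= a_abr_abrupt_m)
    stop("gradual thresholds must lie strictly below abrupt thresholds",
         call. = FALSE)
  structure(th, class = "classification_thresholds")
}

#' Analysis configuration
#'
#' @param crown_ratio crown-diameter-to-height ratio used to fill
#'   missing crown diameters (dimensionless). Only cover/discreteness
#'   outputs depend on it; abruptness uses heights only.
#' @param thresholds a [classification_thresholds()] object.
#' @param supersample subpixels per cover-cell edge for the
#'   union-of-crowns rasterization (deterministic subgrid).
#' @param rng_seed integer seed recorded in reports for provenance.
#' @return An object of class `ecotone_config`.
#' @export
ecotone_config <- function(crown_ratio = 0.5,
                           thresholds = classification_thresholds(),
                           supersample = 10L, rng_seed = 1L) {
  stopifnot(crown_ratio > 0, supersample >= 1)
  if (!inherits(thresholds, "classification_thresholds"))
    stop("thresholds must be a classification_thresholds object",
         call. = FALSE)
  structure(list(crown_ratio = crown_ratio, thresholds = thresholds,
                 supersample = as.integer(supersample),
                 rng_seed = as.integer(rng_seed)),
            class = "ecotone_config")
}

is_whole <- function(x, tol = 1e-8) abs(x - round(x)) < tol
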