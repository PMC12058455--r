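#' Read a tree point pattern from CSV
#'
#' Loads individual-tree records from a comma-separated file with a
#' header row. Required columns: `x` (across-slope, m), `y` (upslope
#' distance from the transect bottom, m), `height` (m). Optional
#' columns: `crown_diameter` (m), `growth_form` (one of `tree`,
#' `krummholz`, `unknown`) and `age` (accepted but unused). Records
#' outside the transect rectangle or with non-positive height are
#' dropped and counted; missing crown diameters are filled as
#' `crown_ratio * height`.
#'
#' @param path CSV file path.
#' @param spec a [transect_spec()].
#' @param config an [ecotone_config()]; supplies `crown_ratio`.
#' @return A data frame of class `tree_records` with columns `x`, `y`,
#'   `height`, `crown_diameter`, `growth_form`, and an attribute
#'   `load_report` listing counts of dropped records.
#' @export
read_point_pattern <- function(path, spec, config = ecotone_config()) {
  stopifnot(inherits(spec, "transect_spec"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("x", "y", "height")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("point-pattern CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(raw) == 0L)
    stop("point-pattern CSV contains no records", call. = FALSE)
  as_tree_records(raw, spec, crown_ratio = config$crown_ratio)
}

#' Validate a data frame of tree records
#'
#' Applies the same validation and crown filling as
#' [read_point_pattern()] to an in-memory data frame.
#'
#' @param trees data frame with columns `x`, `y`, `height` and optional
#'   `crown_diameter`, `growth_form`.
#' @inheritParams read_point_pattern
#' @param crown_ratio ratio used to fill missing crown diameters.
#' @return A `tree_records` data frame (see [read_point_pattern()]).
#' @export
as_tree_records <- function(trees, spec, crown_ratio = 0.5) {
  stopifnot(inherits(spec, "transect_spec"))
  trees <- as.data.frame(trees)
  for (col in c("x", "y", "height"))
    trees[[col]] <- as.numeric(trees[[col]])
  n_in <- nrow(trees)
  oob <- is.na(trees$x) | is.na(trees$y) | trees$x < 0 |
    trees$x > spec$width | trees$y < 0 | trees$y > spec$length
  bad_height <- !oob & (is.na(trees$height) | trees$height <= 0)
  keep <- !oob & !bad_height
  trees <- trees[keep, , drop = FALSE]
  if (nrow(trees) == 0L)
    stop("no valid tree records inside the transect", call. = FALSE)

  if (is.null(trees$crown_diameter)) {
    trees$crown_diameter <- crown_ratio * trees$height
    n_filled <- nrow(trees)
  } else {
    trees$crown_diameter <- as.numeric(trees$crown_diameter)
    fill <- is.na(trees$crown_diameter) | trees$crown_diameter <= 0
    trees$crown_diameter[fill] <- crown_ratio * trees$height[fill]
    n_filled <- sum(fill)
  }
  if (is.null(trees$growth_form)) {
    trees$growth_form <- "unknown"
  } else {
    gf <- tolower(trimws(as.character(trees$growth_form)))
    gf[!gf %in% c("tree", "krummholz")] <- "unknown"
    trees$growth_form <- gf
  }
  trees <- trees[, intersect(c("x", "y", "height", "crown_diameter",
                               "growth_form", "age"), names(trees)),
                 drop = FALSE]
  rownames(trees) <- NULL
  attr(trees, "load_report") <- list(
    n_input = n_in, n_valid = nrow(trees),
    n_out_of_bounds = sum(oob), n_bad_height = sum(bad_height),
    n_crown_filled = n_filled)
  class(trees) <- c("tree_records", "data.frame")
  trees
}

#' Read a gridded tree-cover table
#'
#' Entry point for cover data that did not come from a point pattern
#' (e.g., classified remote-sensing imagery): a CSV of cell-centre
#' coordinates and cover fractions replaces crown rasterization.
#' Columns: `cell_x`, `cell_y` (cell centres, m), `cover` (in \[0, 1\]).
#' The grid must tile the full transect at `spec$cell_size` resolution.
#'
#' @inheritParams read_point_pattern
#' @return A `cover_grid` object (see [rasterize_cover()]).
#' @export
read_cover_grid <- function(path, spec) {
  stopifnot(inherits(spec, "transect_spec"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_x", "cell_y", "cover")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("cover-grid CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  h <- spec$cell_size
  nx <- as.integer(round(spec$width / h))
  ny <- as.integer(round(spec$length / h))
  if (any(raw$cover < 0 | raw$cover > 1, na.rm = TRUE) ||
      anyNA(raw$cover))
    stop("cover values must lie in [0, 1]", call. = FALSE)
  ix <- round(raw$cell_x / h + 0.5)
  iy <- round(raw$cell_y / h + 0.5)
  if (any(abs(raw$cell_x - (ix - 0.5) * h) > 1e-6) ||
      any(abs(raw$cell_y - (iy - 0.5) * h) > 1e-6))
    stop("cell coordinates are not centres of a ", h, "-m grid",
         call. = FALSE)
  if (any(ix < 1 | ix > nx | iy < 1 | iy > ny))
    stop("cell coordinates fall outside the transect", call. = FALSE)
  if (nrow(raw) != nx * ny || anyDuplicated(cbind(ix, iy)))
    stop("cover grid must contain every cell exactly once (expected ",
         nx * ny, " cells, got ", nrow(raw), ")", call. = FALSE)
  cells <- matrix(NA_real_, nrow = nx, ncol = ny)
  cells[cbind(ix, iy)] <- raw$cover
  new_cover_grid(cells, h)
}

#' Write a cover grid to CSV
#'
#' @param grid a `cover_grid` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cover_grid <- function(grid, path) {
  stopifnot(inherits(grid, "cover_grid"))
  h <- grid$cell_size
  nx <- nrow(grid$cells); ny <- ncol(grid$cells)
  df <- data.frame(
    cell_x = rep((seq_len(nx) - 0.5) * h, times = ny),
    cell_y = rep((seq_len(ny) - 0.5) * h, each = nx),
    cover = as.vector(grid$cells))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the JSON analysis report
#'
#' Serializes a full [treeline_metrics()] result: the four abruptness
#' metrics, the fitted logistic parameters, validity flags, class
#' labels, the thresholds used, and all intermediate belt vectors.
#'
#' @param report a `treeline_report` from [treeline_metrics()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "treeline_report"))
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read back a JSON analysis report
#'
#' @param path JSON file written by [write_report()].
#' @return A list mirroring the report structure.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write belt vectors to a flat CSV
#'
#' One row per belt, bottom to top, with the raw, truncated and
#' smoothed canopy-height vectors, the per-belt individual count
#' (diagnostic only) and the belt-mean cover.
#'
#' @inheritParams write_report
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_belt_vectors <- function(report, path) {
  stopifnot(inherits(report, "treeline_report"))
  utils::write.csv(belt_vector_table(report), path, row.names = FALSE)
  invisible(path)
}

belt_vector_table <- function(report) {
  ab <- report$abruptness
  data.frame(
    belt_index = seq_along(ab$Max_H$values),
    midpoint_y = ab$Max_H$midpoints,
    Max_H = ab$Max_H$values,
    Max2_H = ab$Max2_H$values,
    tMax_H = ab$tMax_H$values,
    sMax_H = ab$sMax_H$values,
    tMax2_H = if (is.null(ab$tMax2_H)) NA_real_ else ab$tMax2_H$values,
    sMax2_H = if (is.null(ab$sMax2_H)) NA_real_ else ab$sMax2_H$values,
    n_individuals = report$belt_counts,
    cover_mean = report$belt_cover_mean)
}

# strip S3 classes recursively so jsonlite writes plain structures
unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else if (is.object(x)) unclass(x) else x
}
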