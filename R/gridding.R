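#' Belt-wise summary-statistic vector
#'
#' A numeric vector with one value per elevational belt, indexed from
#' the transect bottom (belt 1) to the top, together with the belt
#' midpoint coordinates and a label naming the statistic.
#'
#' @param values numeric, one value per belt, bottom to top.
#' @param label statistic name (`"Max_H"`, `"Max2_H"`, `"tMax_H"`, ...).
#' @param midpoints y coordinate of each belt centre (m).
#' @return An object of class `belt_vector`.
#' @export
belt_vector <- function(values, label, midpoints) {
  stopifnot(length(values) == length(midpoints))
  structure(list(values = as.numeric(values), label = label,
                 midpoints = as.numeric(midpoints)),
            class = "belt_vector")
}

#' @export
print.belt_vector <- function(x, ...) {
  cat(x$label, " over ", length(x$values), " belts (bottom to top):\n",
      sep = "")
  print(stats::setNames(x$values, format(x$midpoints)))
  invisible(x)
}

# Belt boundaries for a given origin offset. offset = 0 gives the
# regular grid; 0 < offset < belt_width adds a partial bottom belt
# [0, offset) and, usually, a partial top belt. Belts are half-open
# [low, high) except the top belt, which is closed at the transect end.
belt_breaks <- function(spec, offset = 0) {
  stopifnot(offset >= 0, offset < spec$belt_width)
  if (offset == 0) {
    br <- seq(0, spec$length, by = spec$belt_width)
  } else {
    br <- c(0, seq(offset, spec$length, by = spec$belt_width))
    if (br[length(br)] < spec$length) br <- c(br, spec$length)
  }
  br
}

belt_index_of <- function(y, breaks) {
  i <- findInterval(y, breaks, rightmost.closed = TRUE)
  pmin.int(pmax.int(i, 1L), length(breaks) - 1L)
}

#' Assign trees to elevational belts and subplots
#'
#' Every in-bounds tree is assigned to exactly one (belt, subplot)
#' cell. Belts are half-open intervals `[low, high)` except the top
#' belt, which is closed, and likewise for subplots across the slope.
#'
#' @param trees a `tree_records` data frame (see [read_point_pattern()]).
#' @param spec a [transect_spec()].
#' @param offset belt-origin offset (m, `0 <= offset < belt_width`) used
#'   by the belt-shift robustness scan; 0 gives the regular grid.
#' @return The tree data frame with integer columns `belt_index` and
#'   `subplot_index` appended, carrying attributes `n_belts`,
#'   `subplots_per_belt` and `belt_midpoints` for the (possibly
#'   shifted) belt grid.
#' @export
grid_trees <- function(trees, spec, offset = 0) {
  stopifnot(inherits(spec, "transect_spec"))
  trees <- as.data.frame(trees)
  if (any(trees$x < 0 | trees$x > spec$width |
          trees$y < 0 | trees$y > spec$length))
    stop("trees outside the transect; validate with as_tree_records()",
         call. = FALSE)
  breaks <- belt_breaks(spec, offset)
  trees$belt_index <- belt_index_of(trees$y, breaks)
  sub_breaks <- seq(0, spec$width, by = spec$subplot_size)
  trees$subplot_index <- belt_index_of(trees$x, sub_breaks)
  attr(trees, "n_belts") <- length(breaks) - 1L
  attr(trees, "subplots_per_belt") <- spec$subplots_per_belt
  attr(trees, "belt_midpoints") <- (breaks[-length(breaks)] +
                                      breaks[-1]) / 2
  attr(trees, "belt_breaks") <- breaks
  trees
}

#' Subplot canopy heights and individual counts
#'
#' Subplot canopy height is the height of the tallest individual
#' strictly taller than the seedling cutoff within the subplot, or NA
#' if the subplot holds no such individual. Every (belt, subplot) cell
#' of the grid is present in the output, including empty ones.
#'
#' @param gridded output of [grid_trees()].
#' @param spec a [transect_spec()].
#' @return A data frame with columns `belt_index`, `subplot_index`,
#'   `canopy_height` (m or NA) and `n_individuals`.
#' @export
subplot_canopy_heights <- function(gridded, spec) {
  n_belts <- attr(gridded, "n_belts")
  n_sub <- attr(gridded, "subplots_per_belt")
  if (is.null(n_belts))
    stop("gridded must come from grid_trees()", call. = FALSE)
  out <- data.frame(
    belt_index = rep(seq_len(n_belts), each = n_sub),
    subplot_index = rep(seq_len(n_sub), times = n_belts),
    canopy_height = NA_real_, n_individuals = 0L)
  tall <- gridded[gridded$height > spec$seedling_cutoff, , drop = FALSE]
  if (nrow(tall)) {
    cell <- (tall$belt_index - 1L) * n_sub + tall$subplot_index
    hmax <- tapply(tall$height, cell, max)
    cnt <- tapply(tall$height, cell, length)
    idx <- as.integer(names(hmax))
    out$canopy_height[idx] <- as.numeric(hmax)
    out$n_individuals[idx] <- as.integer(cnt)
  }
  attr(out, "belt_midpoints") <- attr(gridded, "belt_midpoints")
  out
}

#' Belt-wise maximum canopy-height vectors
#'
#' Aggregates subplot canopy heights into the two belt-wise data
#' vectors used for abruptness: the highest subplot canopy height per
#' belt (the height of the tallest individual in the belt), set to 0
#' if no individual in the belt exceeds the seedling cutoff; and the
#' second-highest subplot canopy height per belt, set to 0 if fewer
#' than two subplots in the belt hold such individuals. With 12
#' subplots per belt the second vector corresponds to the belt-wise
#' 92nd percentile of subplot canopy height. Two subplots tied for the
#' highest value give equal first and second maxima.
#'
#' @param stats output of [subplot_canopy_heights()].
#' @param spec a [transect_spec()].
#' @return A list with `belt_vector` elements `Max_H` and `Max2_H` and
#'   an integer vector `n_individuals` of per-belt counts (diagnostic).
#' @export
belt_max_vectors <- function(stats, spec) {
  midpoints <- attr(stats, "belt_midpoints")
  n_belts <- max(stats$belt_index)
  if (is.null(midpoints)) midpoints <- spec$belt_midpoints
  max1 <- max2 <- numeric(n_belts)
  for (b in seq_len(n_belts)) {
    ch <- stats$canopy_height[stats$belt_index == b]
    ch <- sort(ch[!is.na(ch)], decreasing = TRUE)
    if (length(ch) >= 1L) max1[b] <- ch[1L]
    if (length(ch) >= 2L) max2[b] <- ch[2L]
  }
  counts <- as.integer(tapply(stats$n_individuals, stats$belt_index, sum))
  list(Max_H = belt_vector(max1, "Max_H", midpoints),
       Max2_H = belt_vector(max2, "Max2_H", midpoints),
       n_individuals = counts)
}
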