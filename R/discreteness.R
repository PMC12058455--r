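new_cover_grid <- function(cells, cell_size) {
  dimnames(cells) <- NULL
  structure(list(cells = cells, cell_size = cell_size),
            class = "cover_grid")
}

#' @export
print.cover_grid <- function(x, ...) {
  cat("Cover grid: ", nrow(x$cells), " x ", ncol(x$cells), " cells of ",
      x$cell_size, " m; mean cover ",
      sprintf("%.3f", mean(x$cells)), "\n", sep = "")
  invisible(x)
}

#' Rasterize union-of-crowns tree cover
#'
#' Projects circular tree crowns onto the transect cell grid and
#' computes, per cell, the fraction of cell area covered by the union
#' of all crown disks (overlap counted once). The fraction is
#' evaluated on a deterministic `supersample` x `supersample` subgrid
#' of points per cell: a subpoint is covered iff it lies inside at
#' least one disk. Crowns are clipped at the transect edges.
#'
#' @param trees a `tree_records` data frame; every tree must have a
#'   positive `crown_diameter`.
#' @param spec a [transect_spec()].
#' @param supersample subpoints per cell edge; 10 keeps the area error
#'   of a metre-scale disk below about 1 percent on 1-m cells.
#' @return An object of class `cover_grid`: a list with `cells` (matrix
#'   of cover fractions, rows = across-slope cells, columns = uphill
#'   cells starting at the transect bottom) and `cell_size`.
#' @export
rasterize_cover <- function(trees, spec, supersample = 10L) {
  stopifnot(inherits(spec, "transect_spec"), supersample >= 1)
  trees <- as.data.frame(trees)
  ss <- as.integer(supersample)
  h <- spec$cell_size
  fine <- h / ss
  nx <- as.integer(round(spec$width / h))
  ny <- as.integer(round(spec$length / h))
  nxf <- nx * ss; nyf <- ny * ss
  covered <- matrix(FALSE, nxf, nyf)
  if (nrow(trees)) {
    if (is.null(trees$crown_diameter) || anyNA(trees$crown_diameter))
      stop("every tree needs a crown_diameter; fill via as_tree_records()",
           call. = FALSE)
    xs <- (seq_len(nxf) - 0.5) * fine
    ys <- (seq_len(nyf) - 0.5) * fine
    for (k in seq_len(nrow(trees))) {
      r <- trees$crown_diameter[k] / 2
      if (r <= 0) next
      cx <- trees$x[k]; cy <- trees$y[k]
      ix_lo <- max(1L, as.integer(ceiling((cx - r) / fine + 0.5)))
      ix_hi <- min(nxf, as.integer(floor((cx + r) / fine + 0.5)))
      iy_lo <- max(1L, as.integer(ceiling((cy - r) / fine + 0.5)))
      iy_hi <- min(nyf, as.integer(floor((cy + r) / fine + 0.5)))
      if (ix_lo > ix_hi || iy_lo > iy_hi) next
      ix <- ix_lo:ix_hi; iy <- iy_lo:iy_hi
      inside <- outer((xs[ix] - cx)^2, (ys[iy] - cy)^2, "+") <= r^2
      covered[ix, iy] <- covered[ix, iy] | inside
    }
  }
  # block-average the fine mask down to cell resolution
  a1 <- rowsum(covered + 0L, rep(seq_len(nx), each = ss))
  a2 <- rowsum(t(a1), rep(seq_len(ny), each = ss))
  new_cover_grid(t(a2) / (ss * ss), h)
}

#' Total covered area of a cover grid
#'
#' @param grid a `cover_grid`.
#' @return Covered area in square metres (sum of cover fractions times
#'   cell area).
#' @export
covered_area <- function(grid) {
  stopifnot(inherits(grid, "cover_grid"))
  sum(grid$cells) * grid$cell_size^2
}

#' Subplot-level mean cover
#'
#' Averages cell cover over each subplot. The y coordinate attached to
#' each subplot is the midpoint of its belt: these (y, cover) points
#' are the data the discreteness logistic is fitted to, one point per
#' subplot so that belts are implicitly weighted by their subplot
#' count.
#'
#' @param grid a `cover_grid` covering the full transect.
#' @param spec a [transect_spec()]; `cell_size` must match the grid and
#'   divide `subplot_size`.
#' @return A data frame with columns `belt_index`, `subplot_index`, `y`
#'   (belt midpoint, m) and `cover`.
#' @export
subplot_mean_cover <- function(grid, spec) {
  stopifnot(inherits(grid, "cover_grid"), inherits(spec, "transect_spec"))
  if (abs(grid$cell_size - spec$cell_size) > 1e-9)
    stop("grid cell_size does not match the transect spec", call. = FALSE)
  k <- spec$subplot_size / grid$cell_size
  kb <- spec$belt_width / grid$cell_size
  if (!is_whole(k) || !is_whole(kb))
    stop("cell_size must divide subplot_size and belt_width", call. = FALSE)
  k <- as.integer(round(k)); kb <- as.integer(round(kb))
  n_sub <- spec$subplots_per_belt; n_belts <- spec$n_belts
  a1 <- rowsum(grid$cells, rep(seq_len(n_sub), each = k))
  a2 <- rowsum(t(a1), rep(seq_len(n_belts), each = kb))  # n_belts x n_sub
  mean_cover <- t(a2) / (k * kb)
  data.frame(
    belt_index = rep(seq_len(n_belts), each = n_sub),
    subplot_index = rep(seq_len(n_sub), times = n_belts),
    y = rep(spec$belt_midpoints, each = n_sub),
    cover = as.vector(mean_cover))
}

#' Logistic cover-transition curve
#'
#' The three-parameter logistic used to model tree cover along the
#' elevational axis, `C(y) = C_max / (1 + exp(s * (y - y_l)))`. With
#' `s > 0` cover decreases uphill; `C(y_l) = C_max / 2`.
#'
#' @param y upslope distance (m).
#' @param c_max asymptotic forest cover (dimensionless).
#' @param y_l transition midpoint (m).
#' @param s transition steepness (per m).
#' @return Cover fraction(s).
#' @export
logistic_cover <- function(y, c_max, y_l, s) c_max / (1 + exp(s * (y - y_l)))

#' Fit the cover-transition logistic and derive discreteness
#'
#' Least-squares fit of [logistic_cover()] to subplot-level cover
#' points along the elevational axis, by Levenberg-Marquardt (damped
#' Gauss-Newton) with steepness constrained non-negative and up to
#' five restarts from jittered steepness starts. The fitted steepness
#' `s` quantifies discreteness. Fits whose transition midpoint lies at
#' or below `y_l_margin_m`, or above the transect top, leave most of
#' the transition outside the sampled area and are flagged
#' non-interpretable; a fitted forest cover below `c_max_min` flags
#' low forest cover (the discreteness concept does not apply, the
#' ecotone is diffuse by default). The fitted forest cover is not
#' capped at 1 even though the data are.
#'
#' @param points data frame with columns `y` (m) and `cover`
#'   (fractions, one row per subplot), e.g. from
#'   [subplot_mean_cover()].
#' @param transect_length transect length (m), for the midpoint validity check.
#' @param thresholds a [classification_thresholds()].
#' @return An object of class `discreteness_result`: fitted `C_max`,
#'   `y_l` (m), `s` (per m), `rss`, `converged`, `status` (one of
#'   `ok`, `midpoint_below_margin`, `midpoint_above_transect`,
#'   `low_forest_cover`, `fit_failed`) and `n_points`. When status is
#'   not `ok`, `s` is carried but not interpretable.
#' @export
fit_cover_logistic <- function(points, transect_length,
                               thresholds = classification_thresholds()) {
  stopifnot(is.data.frame(points), all(c("y", "cover") %in% names(points)))
  points <- points[is.finite(points$y) & is.finite(points$cover), ]
  if (length(unique(points$y)) < 3L)
    stop("need cover points at >= 3 distinct y positions", call. = FALSE)

  ys <- sort(unique(points$y))
  prof <- vapply(ys, function(v) mean(points$cover[points$y == v]),
                 numeric(1))
  c_max0 <- mean(points$cover[points$y <= ys[min(2L, length(ys))]])
  if (c_max0 <= 0) c_max0 <- max(mean(points$cover), 1e-3)
  # monotone (non-increasing uphill) envelope of the profile, then the
  # first y where it falls below half the bottom cover
  mono <- rev(cummax(rev(prof)))
  cross <- which(mono < c_max0 / 2)
  y_l0 <- if (length(cross)) ys[cross[1L]] else transect_length / 2

  best <- NULL
  for (s0 in c(0.1, 0.02, 0.05, 0.2, 0.5)) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        cover ~ c_max / (1 + exp(s * (y - y_l))),
        data = points,
        start = list(c_max = c_max0, y_l = y_l0, s = s0),
        lower = c(c_max = 1e-6, y_l = -10 * transect_length, s = 0),
        upper = c(c_max = 10, y_l = 10 * transect_length, s = 50),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(coef = stats::coef(fit), rss = rss,
                   converged = fit$convInfo$isConv %||% TRUE)
  }

  if (is.null(best)) {
    res <- list(C_max = NA_real_, y_l = NA_real_, s = NA_real_,
                rss = NA_real_, converged = FALSE, status = "fit_failed",
                n_points = nrow(points))
  } else {
    co <- best$coef
    status <-
      if (co[["s"]] < 1e-8) "fit_failed"           # pinned at zero slope
      else if (co[["y_l"]] <= thresholds$y_l_margin_m) "midpoint_below_margin"
      else if (co[["y_l"]] > transect_length) "midpoint_above_transect"
      else if (co[["c_max"]] < thresholds$c_max_min) "low_forest_cover"
      else "ok"
    res <- list(C_max = unname(co[["c_max"]]), y_l = unname(co[["y_l"]]),
                s = unname(co[["s"]]), rss = best$rss,
                converged = isTRUE(best$converged), status = status,
                n_points = nrow(points))
  }
  class(res) <- "discreteness_result"
  res
}

#' @export
print.discreteness_result <- function(x, ...) {
  cat("Cover-transition logistic fit (", x$n_points, " subplot points):\n",
      sep = "")
  s_str <- if (identical(x$status, "ok")) sprintf("%.4f", x$s)
           else sprintf("(%.4f)", x$s)  # parenthesised: not interpretable
  cat(sprintf("  C_max = %.3f   y_l = %.2f m   s = %s per m\n",
              x$C_max, x$y_l, s_str))
  cat("  status:", x$status, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
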