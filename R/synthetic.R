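#' Define a synthetic treeline-ecotone scenario
#'
#' Specifies an idealised ecotone with known ground truth: a canopy
#' height profile (linear decline or a step at full forest height), a
#' logistic target cover profile, an optional krummholz belt, and
#' multiplicative height noise. [generate_ecotone()] realises the
#' scenario as an individual-tree point pattern.
#'
#' @param spec a [transect_spec()].
#' @param form_height `"gradual_linear"` (height declines linearly from
#'   `h_max` at the bottom to 0 at `y_top`) or `"abrupt_step"` (height
#'   is `h_max` below `y_step` and `residual_height` above it).
#' @param h_max forest canopy height at the transect bottom (m).
#' @param y_top for the gradual form: y at which the height profile
#'   reaches 0 (m); defaults to the transect length.
#' @param y_step for the abrupt form: step location (m).
#' @param residual_height height of residual vegetation above an
#'   abrupt step (m); must stay below the seedling cutoff so that it
#'   cannot perturb the abruptness metrics.
#' @param c_max,y_l,s true parameters of the logistic target cover
#'   profile (see [logistic_cover()]); `c_max` in (0, 1], `s >= 0`.
#' @param krummholz optional list `list(y_range = c(lo, hi), cap = m)`:
#'   heights within the range are capped and flagged as krummholz.
#' @param noise relative height noise fraction: realised heights are
#'   `H(y) * (1 - noise * U)` with `U` uniform on (0, 1).
#' @param crown_ratio crown-diameter-to-height ratio of the generated
#'   trees.
#' @param seed integer RNG seed; the generated pattern is a
#'   deterministic function of the scenario including the seed.
#' @return An object of class `ecotone_scenario`.
#' @export
ecotone_scenario <- function(spec = transect_spec(180, 60),
                             form_height = c("gradual_linear",
                                             "abrupt_step"),
                             h_max = 10, y_top = NULL, y_step = NULL,
                             residual_height = 0.3,
                             c_max = 0.6, y_l = 90, s = 0.1,
                             krummholz = NULL, noise = 0.1,
                             crown_ratio = 0.5, seed = 1L) {
  form_height <- match.arg(form_height)
  stopifnot(inherits(spec, "transect_spec"))
  if (h_max <= 0) stop("h_max must be positive", call. = FALSE)
  if (!(c_max > 0 && c_max <= 1))
    stop("c_max must lie in (0, 1]: a target cover above 1 is not ",
         "realisable", call. = FALSE)
  if (s < 0) stop("s must be non-negative", call. = FALSE)
  if (noise < 0 || noise >= 1)
    stop("noise must lie in [0, 1)", call. = FALSE)
  if (form_height == "gradual_linear") {
    if (is.null(y_top)) y_top <- spec$length
    if (y_top <= 0) stop("y_top must be positive", call. = FALSE)
  } else {
    if (is.null(y_step))
      stop("abrupt_step form needs y_step", call. = FALSE)
    if (y_step <= 0 || y_step >= spec$length)
      stop("y_step must lie inside the transect", call. = FALSE)
    if (residual_height >= spec$seedling_cutoff)
      stop("residual_height must stay below the seedling cutoff of ",
           spec$seedling_cutoff, " m", call. = FALSE)
  }
  if (!is.null(krummholz)) {
    if (!is.list(krummholz) || length(krummholz$y_range) != 2L ||
        is.null(krummholz$cap) || krummholz$cap <= 0)
      stop("krummholz must be list(y_range = c(lo, hi), cap = m)",
           call. = FALSE)
  }
  structure(list(spec = spec, form_height = form_height, h_max = h_max,
                 y_top = y_top, y_step = y_step,
                 residual_height = residual_height, c_max = c_max,
                 y_l = y_l, s = s, krummholz = krummholz, noise = noise,
                 crown_ratio = crown_ratio, seed = as.integer(seed)),
            class = "ecotone_scenario")
}

# deterministic height profile of a scenario (no noise)
scenario_height_profile <- function(scenario, y) {
  h <- if (scenario$form_height == "gradual_linear") {
    scenario$h_max * pmax(0, 1 - y / scenario$y_top)
  } else {
    ifelse(y < scenario$y_step, scenario$h_max, scenario$residual_height)
  }
  kh <- scenario$krummholz
  if (!is.null(kh)) {
    inside <- y >= kh$y_range[1] & y <= kh$y_range[2]
    h[inside] <- pmin(h[inside], kh$cap)
  }
  h
}

#' Generate a synthetic ecotone point pattern with known ground truth
#'
#' Places trees by an inhomogeneous Poisson process whose intensity is
#' chosen so that the realised union-of-crowns cover tracks the
#' scenario's logistic target profile: with local expected crown
#' radius `r(y) = crown_ratio * H(y) / 2`, the Boolean (Poisson disk)
#' model realises expected cover `1 - exp(-lambda * pi * r^2)`, so the
#' generator inverts it, `lambda(y) = -log(1 - C(y)) / (pi r(y)^2)`.
#' Where the target cover is unreachable with the local crown size
#' (tiny residual vegetation), the intensity saturates at a ceiling;
#' if that happens where the height profile is of forest stature the
#' scenario is rejected as unrealisable. Heights receive
#' multiplicative noise `(1 - noise * U)`; the caller's RNG state is
#' left untouched.
#'
#' @param scenario an [ecotone_scenario()].
#' @param lambda_max intensity ceiling (trees per square metre).
#' @return A list with `trees` (a `tree_records` data frame) and
#'   `truth` (the scenario's true parameters: `form_height`, `h_max`,
#'   `step_height`, `c_max_true`, `y_l_true`, `s_true`, `seed`).
#' @export
generate_ecotone <- function(scenario, lambda_max = 2) {
  stopifnot(inherits(scenario, "ecotone_scenario"))
  spec <- scenario$spec
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(scenario$seed)

  strip <- 1                                    # 1-m strips along y
  y_lo <- seq(0, spec$length - strip, by = strip)
  y_mid <- y_lo + strip / 2
  H <- scenario_height_profile(scenario, y_mid)
  Ct <- logistic_cover(y_mid, scenario$c_max, scenario$y_l, scenario$s)
  r <- scenario$crown_ratio * H / 2
  # Boolean-model inversion with the expected squared radius of the
  # noised crowns: heights carry a (1 - noise * U) factor, so
  # E[r_realised^2] = r^2 * (1 - noise + noise^2 / 3)
  shrink <- 1 - scenario$noise + scenario$noise^2 / 3
  lam <- numeric(length(y_mid))
  active <- H > 0.01 & Ct > 1e-4
  lam[active] <- -log(1 - pmin(Ct[active], 0.999)) /
    (pi * r[active]^2 * shrink)
  overflow <- lam > lambda_max
  if (any(overflow & H > spec$forest_cutoff))
    stop("intensity overflow: target cover ",
         signif(max(Ct[overflow & H > spec$forest_cutoff]), 3),
         " is not realisable with crowns of forest-stature trees; ",
         "lower c_max or raise h_max / crown_ratio", call. = FALSE)
  lam <- pmin(lam, lambda_max)

  counts <- stats::rpois(length(lam), lam * spec$width * strip)
  n <- sum(counts)
  if (n == 0L)
    stop("scenario generated no trees; increase cover or height",
         call. = FALSE)
  ys <- rep(y_lo, counts) + stats::runif(n, 0, strip)
  xs <- stats::runif(n, 0, spec$width)
  h0 <- scenario_height_profile(scenario, ys)
  heights <- h0 * (1 - scenario$noise * stats::runif(n))
  gf <- rep("tree", n)
  kh <- scenario$krummholz
  if (!is.null(kh))
    gf[ys >= kh$y_range[1] & ys <= kh$y_range[2]] <- "krummholz"
  trees <- data.frame(x = xs, y = ys, height = heights,
                      crown_diameter = scenario$crown_ratio * heights,
                      growth_form = gf)
  trees <- trees[trees$height > 0, , drop = FALSE]
  trees <- as_tree_records(trees, spec,
                           crown_ratio = scenario$crown_ratio)
  truth <- list(form_height = scenario$form_height,
                h_max = scenario$h_max,
                step_height = if (scenario$form_height == "abrupt_step")
                  scenario$h_max else NA_real_,
                c_max_true = scenario$c_max, y_l_true = scenario$y_l,
                s_true = scenario$s, seed = scenario$seed)
  list(trees = trees, truth = truth)
}

#' Hand-traceable belt-vector fixtures
#'
#' Small canonical canopy-height vectors whose truncation, smoothing
#' and abruptness values can be verified by hand; used to exercise the
#' abruptness pipeline without generating point patterns.
#'
#' @return A named list of fixtures. Each fixture holds `values` (the
#'   raw bottom-to-top vector), the `forest_cutoff` it is meant to be
#'   processed with, and the expected `y_t`, `truncated`, `smoothed`,
#'   `a_abr` and `n_abr` (where defined by hand).
#' @export
generate_worked_vectors <- function() {
  list(
    trace1 = list(
      values = c(10, 12, 8, 4, 2, 1, 0), forest_cutoff = 3,
      y_t = 4L, truncated = c(4, 4, 4, 4, 2, 1, 0),
      smoothed = c(4, 4, 4, 4, 2, 1, 0),
      a_abr = 2, n_abr = 2 / 12),
    gap1 = list(
      values = c(4, 4, 4, 4, 0, 2, 0), forest_cutoff = 3,
      y_t = 4L, truncated = c(4, 4, 4, 4, 0, 2, 0),
      smoothed = c(4, 4, 4, 4, 2, 2, 0),
      a_abr = 2, n_abr = 2 / 4),
    gap2 = list(
      values = c(5, 5, 0, 3, 2, 1), forest_cutoff = 3,
      y_t = 2L, truncated = c(5, 5, 0, 3, 2, 1),
      smoothed = c(5, 5, 3, 3, 2, 1),
      a_abr = 2, n_abr = 2 / 5),
    flat = list(
      values = c(5, 5, 5), forest_cutoff = 3,
      y_t = 3L, truncated = c(5, 5, 5), smoothed = c(5, 5, 5),
      a_abr = 0, n_abr = 0),
    one_step = list(
      values = c(8, 8, 0), forest_cutoff = 3,
      y_t = 2L, truncated = c(8, 8, 0), smoothed = c(8, 8, 0),
      a_abr = 8, n_abr = 1))
}

#' Read / write scenario files
#'
#' Scenarios serialise to a flat YAML mapping so that simulation runs
#' can be configured from the command line and reproduced exactly.
#'
#' @param path scenario file path.
#' @return [read_scenario()] returns an [ecotone_scenario()];
#'   [write_scenario()] returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  spec <- transect_spec(
    length = cfg$length %||% 180, width = cfg$width %||% 60,
    belt_width = cfg$belt_width %||% 5,
    subplot_size = cfg$subplot_size %||% 5,
    cell_size = cfg$cell_size %||% 1,
    seedling_cutoff = cfg$seedling_cutoff %||% 0.5,
    forest_cutoff = cfg$forest_cutoff %||% 3)
  krummholz <- if (!is.null(cfg$krummholz_lo))
    list(y_range = c(cfg$krummholz_lo, cfg$krummholz_hi),
         cap = cfg$krummholz_cap)
  ecotone_scenario(
    spec = spec, form_height = cfg$form_height %||% "gradual_linear",
    h_max = cfg$h_max %||% 10, y_top = cfg$y_top,
    y_step = cfg$y_step, residual_height = cfg$residual_height %||% 0.3,
    c_max = cfg$c_max %||% 0.6, y_l = cfg$y_l %||% 90,
    s = cfg$s %||% 0.1, krummholz = krummholz,
    noise = cfg$noise %||% 0.1, crown_ratio = cfg$crown_ratio %||% 0.5,
    seed = cfg$seed %||% 1L)
}

#' @rdname read_scenario
#' @param scenario an [ecotone_scenario()].
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "ecotone_scenario"))
  spec <- scenario$spec
  flat <- list(length = spec$length, width = spec$width,
               belt_width = spec$belt_width,
               subplot_size = spec$subplot_size,
               cell_size = spec$cell_size,
               seedling_cutoff = spec$seedling_cutoff,
               forest_cutoff = spec$forest_cutoff,
               form_height = scenario$form_height,
               h_max = scenario$h_max, y_top = scenario$y_top,
               y_step = scenario$y_step,
               residual_height = scenario$residual_height,
               c_max = scenario$c_max, y_l = scenario$y_l,
               s = scenario$s, noise = scenario$noise,
               crown_ratio = scenario$crown_ratio,
               seed = scenario$seed)
  if (!is.null(scenario$krummholz)) {
    flat$krummholz_lo <- scenario$krummholz$y_range[1]
    flat$krummholz_hi <- scenario$krummholz$y_range[2]
    flat$krummholz_cap <- scenario$krummholz$cap
  }
  yaml::write_yaml(flat[!vapply(flat, is.null, logical(1))], path)
  invisible(path)
}
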