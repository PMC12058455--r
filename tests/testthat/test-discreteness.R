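test_that("rasterized disk area matches the closed form within 2%", {
  spec <- transect_spec(40, 40)
  disk <- make_trees(x = 20, y = 20, height = 8, crown_diameter = 10,
                     spec = spec)
  grid <- rasterize_cover(disk, spec, supersample = 10)
  r <- 5
  expect_lt(abs(covered_area(grid) - pi * r^2) / (pi * r^2), 0.02)
  expect_true(all(grid$cells >= 0 & grid$cells <= 1))
})

test_that("union cover is idempotent, monotone, and clipped at edges", {
  spec <- transect_spec(40, 40)
  one <- make_trees(x = 20, y = 20, height = 8, crown_diameter = 10,
                    spec = spec)
  two <- make_trees(x = c(20, 20), y = c(20, 20), height = c(8, 8),
                    crown_diameter = c(10, 10), spec = spec)
  expect_identical(rasterize_cover(one, spec, 8)$cells,
                   rasterize_cover(two, spec, 8)$cells)

  # adding a tree never decreases any cell
  more <- make_trees(x = c(20, 30), y = c(20, 10), height = c(8, 6),
                     crown_diameter = c(10, 6), spec = spec)
  g1 <- rasterize_cover(one, spec, 8)
  g2 <- rasterize_cover(more, spec, 8)
  expect_true(all(g2$cells >= g1$cells))

  # crown centred on the transect corner: only a quarter disk remains
  corner <- make_trees(x = 0, y = 0, height = 8, crown_diameter = 10,
                       spec = spec)
  gc_area <- covered_area(rasterize_cover(corner, spec, 10))
  expect_lt(abs(gc_area - pi * 25 / 4) / (pi * 25 / 4), 0.03)

  # no trees: all cells zero (vacuous pattern is rejected upstream,
  # so call the rasterizer on an empty frame directly)
  empty <- data.frame(x = numeric(), y = numeric(), height = numeric(),
                      crown_diameter = numeric())
  expect_true(all(rasterize_cover(empty, spec, 5)$cells == 0))
})

test_that("covered area is invariant under whole-metre translation", {
  spec <- transect_spec(40, 40)
  set.seed(3)
  base <- data.frame(x = runif(10, 8, 15), y = runif(10, 8, 15),
                     height = runif(10, 4, 8))
  t1 <- as_tree_records(base, spec)
  shifted <- base; shifted$x <- base$x + 7; shifted$y <- base$y + 12
  t2 <- as_tree_records(shifted, spec)
  expect_equal(covered_area(rasterize_cover(t1, spec, 10)),
               covered_area(rasterize_cover(t2, spec, 10)))
})

test_that("a 10-m crown at a subplot centre fully covers that subplot", {
  spec <- transect_spec(40, 40)
  # subplot centred at (7.5, 7.5); max corner distance sqrt(2)*2.5 < 5
  tr <- make_trees(x = 7.5, y = 7.5, height = 8, crown_diameter = 10,
                   spec = spec)
  cov <- subplot_mean_cover(rasterize_cover(tr, spec, 10), spec)
  expect_equal(cov$cover[cov$belt_index == 2 & cov$subplot_index == 2], 1.0)
})

test_that("subplot means are plain cell averages", {
  spec <- transect_spec(10, 10)
  # checkerboard grid via the cover-grid CSV entry point
  nx <- 10; ny <- 10
  df <- expand.grid(cell_x = (1:nx) - 0.5, cell_y = (1:ny) - 0.5)
  df$cover <- as.numeric((floor(df$cell_x) + floor(df$cell_y)) %% 2 == 0)
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  grid <- read_cover_grid(path, spec)
  cov <- subplot_mean_cover(grid, spec)
  expect_true(all(cov$cover %in% c(12 / 25, 13 / 25)))

  # uniform grid: every subplot inherits the value
  df$cover <- 0.4
  write.csv(df, path, row.names = FALSE)
  expect_true(all(subplot_mean_cover(read_cover_grid(path, spec),
                                     spec)$cover == 0.4))
})

test_that("cover-grid CSV round-trips to identical downstream fits", {
  spec <- transect_spec(60, 20)
  set.seed(8)
  trees <- make_trees(x = runif(150, 0, 20), y = runif(150, 0, 60),
                      height = pmax(0.3, 9 * (1 - runif(150, 0, 60) / 70)),
                      spec = spec)
  grid <- rasterize_cover(trees, spec, 10)
  path <- tempfile(fileext = ".csv")
  write_cover_grid(grid, path)
  back <- read_cover_grid(path, spec)
  expect_equal(back$cells, grid$cells)
  f1 <- fit_cover_logistic(subplot_mean_cover(grid, spec), spec$length)
  f2 <- fit_cover_logistic(subplot_mean_cover(back, spec), spec$length)
  expect_identical(f1$s, f2$s)

  # malformed grids are rejected
  bad <- read.csv(path); bad$cover[1] <- 1.2
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_cover_grid(path, spec), "\\[0, 1\\]")
  bad$cover[1] <- 0.5
  write.csv(bad[-2, ], path, row.names = FALSE)
  expect_error(read_cover_grid(path, spec), "every cell exactly once")
})

test_that("noiseless logistic data are recovered to 1e-6 relative error", {
  spec <- transect_spec(180, 60)
  truth <- c(c_max = 0.8, y_l = 90, s = 0.3)
  pts <- expand.grid(y = spec$belt_midpoints, sub = 1:12)
  pts$cover <- logistic_cover(pts$y, truth["c_max"], truth["y_l"],
                              truth["s"])
  fit <- fit_cover_logistic(pts, spec$length)
  expect_identical(fit$status, "ok")
  expect_lt(abs(fit$C_max - truth[["c_max"]]) / truth[["c_max"]], 1e-6)
  expect_lt(abs(fit$y_l - truth[["y_l"]]) / truth[["y_l"]], 1e-6)
  expect_lt(abs(fit$s - truth[["s"]]) / truth[["s"]], 1e-6)
  # the fitted curve passes through half cover at the midpoint
  expect_equal(logistic_cover(fit$y_l, fit$C_max, fit$y_l, fit$s),
               fit$C_max / 2)
})

test_that("the fit agrees with an independent optimiser on exact data", {
  spec <- transect_spec(100, 20)
  pts <- expand.grid(y = spec$belt_midpoints, sub = 1:4)
  pts$cover <- logistic_cover(pts$y, 0.7, 55, 0.15)
  fit <- fit_cover_logistic(pts, spec$length)
  rss <- function(p) sum((pts$cover - p[1] / (1 + exp(p[3] * (pts$y -
                                                               p[2]))))^2)
  alt <- optim(c(0.5, 40, 0.05), rss,
               control = list(maxit = 5000, reltol = 1e-14))
  expect_lt(abs(fit$C_max - alt$par[1]), 1e-3)
  expect_lt(abs(fit$y_l - alt$par[2]), 0.1)
  expect_lt(abs(fit$s - alt$par[3]), 1e-3)
})

test_that("validity rules fire on midpoint and forest-cover violations", {
  spec <- transect_spec(180, 60)
  mk <- function(c_max, y_l, s) {
    pts <- expand.grid(y = spec$belt_midpoints, sub = 1:12)
    pts$cover <- pmin(1, logistic_cover(pts$y, c_max, y_l, s))
    fit_cover_logistic(pts, spec$length)
  }
  expect_identical(mk(0.8, 3, 0.1)$status, "midpoint_below_margin")
  expect_identical(mk(0.8, 190, 0.1)$status, "midpoint_above_transect")
  low <- mk(0.28, 90, 0.1)
  expect_identical(low$status, "low_forest_cover")
  expect_identical(classify_discreteness(low)$label, "diffuse")

  # constant cover: steepness unidentifiable
  flat <- expand.grid(y = spec$belt_midpoints, sub = 1:12)
  flat$cover <- 0.3
  ffit <- fit_cover_logistic(flat, spec$length)
  expect_true(ffit$status %in% c("fit_failed", "low_forest_cover",
                                 "midpoint_below_margin",
                                 "midpoint_above_transect"))
  expect_false(classify_discreteness(ffit)$label == "discrete")
})

test_that("the discreteness cut confines the transition to about three belts", {
  # 80%-to-20% transition width of the fitted logistic is 2*ln(4)/s
  s_cut <- classification_thresholds()$s_discrete
  width_at_cut <- 2 * log(4) / s_cut
  expect_lt(width_at_cut, 13.9)
  # any fit at or above the cut has a narrower transition
  expect_lt(2 * log(4) / 0.3, width_at_cut)
})
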