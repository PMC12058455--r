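mk_bv <- function(values, label = "Max_H", belt_width = 5)
  belt_vector(values, label, (seq_along(values) - 0.5) * belt_width)

test_that("truncation finds the topmost forest belt and caps below it", {
  fx <- generate_worked_vectors()
  for (name in names(fx)) {
    f <- fx[[name]]
    tr <- truncate_canopy(mk_bv(f$values), f$forest_cutoff)
    expect_equal(tr$y_t, f$y_t, info = name)
    expect_equal(tr$vector$values, f$truncated, info = name)
  }
  # entirely above the cutoff: truncation belt is the top belt
  tr <- truncate_canopy(mk_bv(c(5, 6, 7)), 3)
  expect_equal(tr$y_t, 3L)
  expect_equal(tr$vector$values, c(7, 7, 7))
  # cutoff never exceeded
  expect_error(truncate_canopy(mk_bv(c(2, 2, 1, 0)), 3), "no-forest")
})

test_that("smoothing fills gaps downhill from the top and is conservative", {
  fx <- generate_worked_vectors()
  for (name in names(fx)) {
    f <- fx[[name]]
    tr <- truncate_canopy(mk_bv(f$values), f$forest_cutoff)
    sm <- smooth_canopy(tr$vector, tr$y_t)
    expect_equal(sm$values, f$smoothed, info = name)
    # never decreases a value, never touches belts at or below y_t
    expect_true(all(sm$values >= tr$vector$values), info = name)
    expect_equal(sm$values[seq_len(tr$y_t)],
                 tr$vector$values[seq_len(tr$y_t)], info = name)
    # non-increasing uphill of the truncation belt
    upper <- sm$values[tr$y_t:length(sm$values)]
    expect_true(all(diff(upper) <= 0), info = name)
  }
})

test_that("abruptness metrics reproduce the hand-traced fixtures", {
  fx <- generate_worked_vectors()
  for (name in names(fx)) {
    f <- fx[[name]]
    ab <- abruptness_metrics(mk_bv(f$values), mk_bv(f$values, "Max2_H"),
                             transect_spec(5 * length(f$values), 5))
    expect_equal(ab$a_abr, f$a_abr, info = name)
    expect_equal(ab$n_abr, f$n_abr, info = name)
  }
  # worked difference example: normalisation uses the raw-vector maximum
  ab <- abruptness_metrics(mk_bv(c(10, 12, 8, 4, 2, 1, 0)),
                           mk_bv(c(9, 10, 7, 3, 1, 0, 0), "Max2_H"),
                           transect_spec(35, 5))
  expect_equal(ab$sMax_H$values, c(4, 4, 4, 4, 2, 1, 0))
  expect_equal(ab$a_abr, 2)
  expect_equal(ab$n_abr, 2 / 12)
  expect_equal(ab$argmax_belt, 4L)       # lowest belt attaining the drop
})

test_that("metrics agree bit-exactly with an independent oracle on 1000 vectors", {
  set.seed(20250922)
  spec_for <- function(n) transect_spec(5 * n, 5)
  n_checked <- 0L
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    v <- random_canopy_vector(n)
    oracle <- oracle_abruptness(v, 3)
    if (is.null(oracle)) {
      expect_error(truncate_canopy(mk_bv(v), 3), "no-forest")
      next
    }
    ab <- abruptness_metrics(mk_bv(v), mk_bv(v, "Max2_H"), spec_for(n))
    expect_identical(ab$y_t, oracle$y_t)
    expect_identical(ab$tMax_H$values, oracle$truncated)
    expect_identical(ab$sMax_H$values, oracle$smoothed)
    expect_identical(ab$a_abr, oracle$a_abr)
    expect_identical(ab$n_abr, oracle$n_abr)
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 800L)
})

test_that("normalised and absolute metrics share the algebraic identity", {
  set.seed(99)
  for (i in 1:50) {
    v <- random_canopy_vector(sample(5:30, 1))
    if (max(v) <= 3) next
    ab <- abruptness_metrics(mk_bv(v), mk_bv(v, "Max2_H"),
                             transect_spec(5 * length(v), 5))
    expect_equal(ab$n_abr, ab$a_abr / max(v))
    expect_gte(ab$n_abr, 0); expect_lte(ab$n_abr, 1)
    expect_gte(ab$a_abr, 0); expect_lte(ab$a_abr, max(v))
  }
})

test_that("degenerate profiles give zero or maximal abruptness", {
  spec <- transect_spec(15, 5)
  flat <- abruptness_metrics(mk_bv(c(5, 5, 5)), mk_bv(c(5, 5, 5), "Max2_H"),
                             spec)
  expect_equal(flat$a_abr, 0)
  expect_equal(flat$n_abr, 0)
  expect_true(flat$edge_truncated)       # canopy persists at the top belt

  cliff <- abruptness_metrics(mk_bv(c(8, 8, 0)), mk_bv(c(8, 8, 0), "Max2_H"),
                              spec)
  expect_equal(cliff$a_abr, 8)
  expect_equal(cliff$n_abr, 1)
  expect_false(cliff$edge_truncated)
})

test_that("an undefined second-maximum vector is reported as such", {
  spec <- transect_spec(20, 5)
  ab <- abruptness_metrics(mk_bv(c(6, 5, 2, 0)),
                           mk_bv(c(2, 1, 0, 0), "Max2_H"), spec)
  expect_true(is.na(ab$a_abr2))
  expect_true(is.na(ab$n_abr2))
  expect_false(is.na(ab$a_abr))
  cls <- classify_abruptness(ab)
  expect_identical(cls$by_metric$a_abr2, "undefined")
})

test_that("a_abr per metre follows the belt width", {
  expect_equal(decline_per_meter(2, 5), 0.4)
  expect_equal(decline_per_meter(2, 10), 0.2)
})

test_that("belt-shift scan separates single-step from spread declines", {
  spec <- transect_spec(60, 20)
  set.seed(31)
  # abrupt: dense 8-m forest up to y = 33 (belt-interior), bare above
  n <- 300
  abrupt <- make_trees(x = runif(n, 0, 20), y = runif(n, 0, 33),
                       height = runif(n, 7, 8), spec = spec)
  scan_a <- belt_shift_scan(abrupt, spec, step = 1)
  rng_a <- scan_a$summary$range[scan_a$summary$metric == "a_abr"]
  expect_lt(rng_a, 1.1)                  # drop seen fully at every offset
  expect_true(all(scan_a$metrics$value[scan_a$metrics$metric == "a_abr"] > 6.9))

  # uniform forest with no decline: every offset gives a_abr = 0
  uniform <- make_trees(x = runif(n, 0, 20), y = runif(n, 0, 60),
                        height = rep(8, n), spec = spec)
  scan_u <- belt_shift_scan(uniform, spec, step = 1)
  expect_true(all(scan_u$metrics$value[scan_u$metrics$metric == "a_abr"] == 0))
  expect_equal(scan_u$summary$range, c(0, 0))
  expect_error(belt_shift_scan(uniform, spec, step = 3), "divide")
})
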