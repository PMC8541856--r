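# Detection scoring and sample-size utilities.

test_that("identical tracks match perfectly at any tolerance", {
  ev <- sort(sample.int(10000, 50))
  for (tol in c(1, 10, 75)) {
    m <- match_events(ev, ev, tol)
    expect_identical(m$tp, 50L)
    expect_identical(m$fp, 0L)
    expect_identical(m$fn, 0L)
  }
  sc <- detection_score(50, 0, 0)
  expect_equal(c(sc$se, sc$pp, sc$er), c(100, 100, 0))
})

test_that("a shift beyond tolerance breaks every match", {
  ev <- seq(100, 2000, by = 100)
  m <- match_events(ev + 20, ev, tol = 19)
  expect_identical(m$tp, 0L)
  expect_identical(m$fp, length(ev))
  expect_identical(m$fn, length(ev))
})

test_that("greedy matching tracks the optimal-assignment oracle", {
  frozen <- list(
    list(seed = 1, greedy = 52L, optimal = 54L),
    list(seed = 2, greedy = 58L, optimal = 59L),
    list(seed = 3, greedy = 54L, optimal = 56L)
  )
  for (fz in frozen) {
    set.seed(fz$seed)
    d <- runif(100, 0, 1000)
    t <- runif(100, 0, 1000)
    m <- match_events(d, t, 5)
    expect_identical(m$tp, fz$greedy)
    expect_identical(oracle_optimal_matches(d, t, 5), fz$optimal)
    # documented greedy/optimal gap on dense random tracks
    expect_lte(fz$optimal - m$tp, 2)
  }
})

test_that("match is symmetric in count roles", {
  set.seed(4)
  d <- runif(60, 0, 1000)
  t <- runif(80, 0, 1000)
  m1 <- match_events(d, t, 10)
  m2 <- match_events(t, d, 10)
  expect_identical(m1$tp, m2$tp)
  expect_identical(m1$fp, m2$fn)
  expect_identical(m1$fn, m2$fp)
})

test_that("scores implement the Se/Pp/Er definitions", {
  sc <- detection_score(99, 2, 1)
  expect_equal(sc$se, 99.0)
  expect_equal(sc$pp, 100 * 99 / 101)
  expect_equal(sc$er, 3.0)

  fp_only <- detection_score(10, 2, 0)
  expect_equal(fp_only$se, 100)
  expect_lt(fp_only$pp, 100)
  expect_gt(fp_only$er, 0)

  expect_error(detection_score(0, 5, 0), "Undefined sensitivity")
  expect_error(match_events(1:3, 1:3, tol = 0), "positive")

  alt <- detection_score(99, 2, 1, config = ecg_config(eval = list(er_denominator = "tp_fp_fn")))
  expect_equal(alt$er, 100 * 3 / 102)
})

test_that("Er decomposes into the miss and false-alarm terms", {
  set.seed(8)
  for (k in 1:20) {
    tp <- sample(50:200, 1)
    fp <- sample(0:20, 1)
    fn <- sample(0:20, 1)
    sc <- detection_score(tp, fp, fn)
    expect_equal(sc$er, (100 - sc$se) + 100 * fp / (tp + fn))
  }
})

test_that("tidiers return the score in long and wide form", {
  sc <- detection_score(99, 2, 1)
  td <- tidy(sc)
  expect_identical(td$value[td$metric == "tp"], 99)
  gl <- glance(sc)
  expect_identical(gl$fp, 2L)
  expect_equal(gl$er, 3.0)
})

test_that("sample-size formulas round up with a floor of one", {
  expect_identical(sample_size_total(1.96, 0.5, 0.155), 40L)
  expect_identical(sample_size_group(1.96, 0.5, 0.31), 10L)
  expect_identical(sample_size_total(1.96, 0.5, 1e6), 1L)
  expect_error(sample_size_total(1.96, 1.5, 0.1), "p in")
  expect_error(sample_size_group(1.96, -0.5, 0.1), "positive")
  # monotone decreasing in the error margin
  ns <- vapply(c(0.05, 0.1, 0.2), function(e) sample_size_total(1.96, 0.5, e), integer(1))
  expect_true(all(diff(ns) < 0))
})
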