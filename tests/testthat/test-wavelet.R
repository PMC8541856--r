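# Wavelet core: transform identities, extrema and zero crossings.

test_that("the transform annihilates constants and is linear", {
  w <- ecg_wavelet(rep(4.2, 500), scales = 5)
  expect_lt(max(abs(unlist(w$w))), 1e-9)

  set.seed(11)
  x <- rnorm(500)
  wa <- ecg_wavelet(x, scales = 5)
  wb <- ecg_wavelet(3.5 * x, scales = 5)
  for (j in 1:5) {
    expect_lt(max(abs(wb$w[[j]] - 3.5 * wa$w[[j]])) / max(abs(wb$w[[j]])), 1e-9)
  }
})

test_that("a Gaussian bump gives one dominant pair with its zero crossing at the peak", {
  fs <- 250
  tt <- (0:999) / fs
  x <- 0.15 * exp(-(tt - 2)^2 / (2 * 0.018^2))
  w <- ecg_wavelet(x, scales = 5)
  for (j in 2:5) {
    ex <- find_extrema(w, j)
    ex <- ex[abs(ex$amplitude) > 0.2 * max(abs(ex$amplitude)), ]
    expect_identical(nrow(ex), 2L)
    expect_gt(ex$amplitude[1], 0)
    expect_lt(ex$amplitude[2], 0)
    z <- zero_crossing(w, ex$index[1], ex$index[2], j)
    expect_lte(abs(z - 500L), 1)
  }
})

test_that("shifting the input shifts the extrema (shift covariance)", {
  fs <- 250
  tt <- (0:999) / fs
  x <- 0.2 * exp(-(tt - 2)^2 / (2 * 0.02^2))
  x2 <- c(numeric(7), x[1:(length(x) - 7)])
  strip <- function(w) {
    ex <- find_extrema(w, 4, 300, 700)
    ex[abs(ex$amplitude) > 0.2 * max(abs(ex$amplitude)), ]
  }
  ea <- strip(ecg_wavelet(x, 4))
  eb <- strip(ecg_wavelet(x2, 4))
  expect_identical(eb$index, ea$index + 7L)
})

test_that("find_extrema matches the exhaustive neighbor-comparison oracle", {
  set.seed(99)
  w <- cumsum(rnorm(1000)) # correlated series with many extrema
  got <- find_extrema(w)
  want <- oracle_extrema(w)
  expect_identical(got$index, as.integer(want$index))
  expect_identical(got$amplitude, want$amplitude)

  expect_identical(nrow(find_extrema(1:100)), 0L) # monotone ramp
  ex <- find_extrema(c(0, 2, 0, -3, 0))
  expect_identical(ex$amplitude, c(2, -3))
  expect_identical(nrow(find_extrema(w, from = 600, to = 400)), 0L)
})

test_that("zero_crossing interpolates and enforces its contract", {
  w <- c(0, 4, 2, -2, -4, 0)
  expect_identical(zero_crossing(w, 1L, 4L), 2L)
  expect_error(zero_crossing(c(0, 2, 1, 3, 0), 1L, 3L), "same sign")
  expect_error(zero_crossing(w, 2L, 2L), "distinct")
})

test_that("too-short signals are rejected with the minimum length", {
  expect_error(ecg_wavelet(rnorm(20), scales = 5), "at least")
})
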