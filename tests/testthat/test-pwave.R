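# P-wave search segments, thresholds, pair screening and delineation.

fake_qrs <- function(onset, r_peak, offset) {
  q <- tibble::tibble(
    beat = seq_along(onset), onset = as.integer(onset),
    r_peak = as.integer(r_peak), offset = as.integer(offset), strength = 1
  )
  attr(q, "fs") <- 250
  class(q) <- c("qrs_tbl", class(q))
  q
}

test_that("search segment follows the stated pre-QRS geometry", {
  q <- fake_qrs(c(500, 1000), c(757, 1007), c(780, 1030))
  seg <- search_segment(q, 2, fs = 250)
  expect_identical(seg$start, 888L) # S_Q - 0.45 s (RR 1.0 caps at 0.45)
  expect_identical(seg$end, 993L) # S_Q - 0.03 s
  expect_false(seg$degenerate)

  # short preceding RR shrinks the window to 0.9 x RR
  q2 <- fake_qrs(c(500, 1000), c(885, 1007), c(889, 1030))
  seg2 <- search_segment(q2, 2, fs = 250)
  expect_identical(seg2$start, as.integer(1000L - floor(0.9 * (1007 - 885))))

  # a first beat too close to the record start has no usable segment
  q3 <- fake_qrs(12, 19, 40)
  expect_true(search_segment(q3, 1, fs = 250)$degenerate)
  expect_error(search_segment(q3, 5, fs = 250), "No such")
})

test_that("thresholds implement the 2/5 and 1/3 top-ten means", {
  ex <- function(amp) tibble::tibble(index = seq_along(amp), amplitude = amp, scale = 4L)
  thr <- p_thresholds(ex(c(rep(1, 10), rep(-0.9, 10))))
  expect_equal(thr$px, 0.4)
  expect_equal(thr$py, -0.3)

  thr2 <- p_thresholds(ex(10:1))
  expect_equal(thr2$px, 0.4 * mean(10:1)) # = 2.2
  expect_equal(thr2$px, 2.2)

  # more than ten extrema: only the ten largest enter the mean
  amps <- c(10:1, 0.5, 0.2)
  thr3 <- p_thresholds(ex(amps))
  expect_equal(thr3$px, 0.4 * mean(sort(amps[amps > 0], decreasing = TRUE)[1:10]))

  # sentinel gates reject everything when one polarity is missing
  thr4 <- p_thresholds(ex(c(1, 2, 3)))
  expect_identical(thr4$py, -Inf)
  pairs <- screen_pairs(ex(c(1, 2, 3)), thr4, fs = 250)
  expect_identical(nrow(pairs), 0L)
})

test_that("pair screening applies the amplitude gates and the 100 ms window", {
  thr <- list(px = 1, py = -1)
  ex <- function(idx, amp) tibble::tibble(index = idx, amplitude = amp, scale = 4L)
  ok <- screen_pairs(ex(c(100L, 120L), c(2.4, -2.2)), thr, fs = 250) # 80 ms
  expect_identical(nrow(ok), 1L)
  expect_equal(ok$interval_ms, 80)
  expect_equal(ok$strength, 4.6)

  too_far <- screen_pairs(ex(c(100L, 130L), c(2.4, -2.2)), thr, fs = 250) # 120 ms
  expect_identical(nrow(too_far), 0L)

  weak_a <- screen_pairs(ex(c(100L, 120L), c(0.5, -2.2)), thr, fs = 250)
  expect_identical(nrow(weak_a), 0L)

  # sub-gate ripple between the pair members does not break adjacency
  ripple <- screen_pairs(
    ex(c(100L, 108L, 112L, 120L), c(2.4, -0.3, 0.2, -2.2)), thr,
    fs = 250
  )
  expect_identical(nrow(ripple), 1L)
  expect_identical(ripple$a_idx, 100L)
  expect_identical(ripple$b_idx, 120L)
})

test_that("pair slope is a signed amplitude difference per millisecond", {
  expect_equal(pair_slope(2.0, -1.0, 100, 160), -0.05)
  expect_equal(pair_slope(4.0, -2.0, 100, 160), 2 * pair_slope(2.0, -1.0, 100, 160))
  expect_error(pair_slope(1, -1, 50, 50), "zero time")
})

test_that("locate_p reports the strongest pair's crossing, one P per segment", {
  fs <- 250
  tt <- (0:999) / fs
  x <- 0.1 * exp(-(tt - 1.6)^2 / (2 * 0.018^2)) +
    0.2 * exp(-(tt - 1.92)^2 / (2 * 0.018^2))
  wt <- ecg_wavelet(x, 4)
  seg <- list(start = 300L, end = 560L, degenerate = FALSE)
  p <- locate_p(wt, seg, fs)
  expect_lte(abs(p$peak - 480L), 2) # the larger bump wins
  expect_true(p$onset < p$peak && p$peak < p$offset)

  expect_null(locate_p(wt, list(start = 0L, end = 200L, degenerate = TRUE), fs))
})

test_that("noiseless primary P peaks and T peaks track the generator truth", {
  sim <- sim_sinus()
  fid <- fid_of("sinus", sim_sinus)
  tp <- sim$truth[sim$truth$wave == "P", ]
  tt <- sim$truth[sim$truth$wave == "T", ]
  pri <- fid[fid$source == "primary", ]
  expect_identical(nrow(pri), nrow(tp))
  expect_true(all(abs(pri$p_peak - tp$peak) <= 2))
  expect_true(all(abs(pri$t_peak - tt$peak) <= 3, na.rm = TRUE))
  expect_identical(sum(!is.na(fid$t_peak)), nrow(tt))
})

test_that("dropped-QRS cycles emit a P but no T for the dropped beat", {
  sim <- sim_dropped()
  fid <- fid_of("dropped", sim_dropped)
  expect_identical(sum(!is.na(fid$p_peak)), sum(sim$truth$wave == "P"))
  expect_identical(sum(!is.na(fid$t_peak)), sum(sim$truth$wave == "T"))
  lone <- fid[is.na(fid$r_peak), ]
  expect_true(all(is.na(lone$t_peak)))
  expect_gte(nrow(lone), 10)
})

test_that("delineation is deterministic and invariant to amplitude scaling", {
  sim <- generate_ecg(rhythm_script("sinus",
    atrial_interval = 0.8, duration = 30,
    noise = noise_spec(snr_db = 20, baseline_amp = 0.1), seed = 2
  ))
  f1 <- delineate(sim$record)
  f2 <- delineate(sim$record)
  expect_identical(as.data.frame(f1), as.data.frame(f2))

  scaled <- sim$record
  scaled$MLII <- scaled$MLII * 7.3
  f3 <- delineate(scaled)
  expect_identical(f1$p_peak, f3$p_peak)
  expect_identical(f1$r_peak, f3$r_peak)
})

test_that("an empty record delineates to an empty fiducial table", {
  rec <- ecg_record(matrix(numeric(0), ncol = 1), fs = 250)
  fid <- delineate(rec)
  expect_identical(nrow(fid), 0L)
  expect_s3_class(fid, "ecg_fiducials")
})

test_that("noisy sinus delineation keeps Se and Pp at 99% or better", {
  sim <- generate_ecg(rhythm_script("sinus",
    atrial_interval = 0.8, duration = 80,
    noise = noise_spec(snr_db = 20), seed = 1
  ))
  fid <- delineate(sim$record)
  sc <- score_detection(fid, sim$truth, "P")
  expect_gte(sc$se, 99)
  expect_gte(sc$pp, 99)
})

test_that("AV dissociation recovers the atrial census through the secondary scan", {
  sim <- sim_dissoc()
  fid <- fid_of("dissoc", sim_dissoc)
  expect_lte(abs(sum(!is.na(fid$p_peak)) - sum(sim$truth$wave == "P")), 1)
  expect_lte(abs(sum(!is.na(fid$r_peak)) - sum(sim$truth$wave == "QRS")), 1)
  expect_gt(sum(fid$source == "secondary"), 0)
})
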