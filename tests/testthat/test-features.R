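# Fiducial features: intervals, durations, dispersion, rates, amplitudes.

test_that("PR interval converts samples to ms with inclusive 120-200 flags", {
  expect_equal(pr_interval(540, 500, 250), tibble::tibble(pr_ms = 160, pr_normal = TRUE))
  expect_true(pr_interval(530, 500, 250)$pr_normal) # 120 ms boundary
  expect_true(pr_interval(550, 500, 250)$pr_normal) # 200 ms boundary
  v <- pr_interval(560, 500, 250)
  expect_equal(v$pr_ms, 240)
  expect_false(v$pr_normal)
  expect_error(pr_interval(500, 500, 250), "S_Q > S_P")
})

test_that("P duration flags the strict 120 ms limit", {
  expect_equal(p_duration(100, 125, 250)$p_dur_ms, 100)
  expect_true(p_duration(100, 125, 250)$p_dur_normal)
  v <- p_duration(0, 30, 250) # exactly 120 ms
  expect_equal(v$p_dur_ms, 120)
  expect_false(v$p_dur_normal)
  expect_error(p_duration(100, 100, 250), "E_P > S_P")
})

test_that("dispersion is max minus min with 40/50 ms flags", {
  v <- p_dispersion(c(110, 95, 80))
  expect_equal(v$pwd_ms, 30)
  expect_true(v$pwd_normal)
  expect_false(v$pwd_heterogeneous)
  expect_equal(p_dispersion(c(100, 100, 100))$pwd_ms, 0)
  v2 <- p_dispersion(c(120, 70))
  expect_equal(v2$pwd_ms, 50)
  expect_false(v2$pwd_normal)
  expect_true(v2$pwd_heterogeneous)
  expect_error(p_dispersion(c(100)), "2 leads")
  # permutation invariance and nonnegativity
  set.seed(5)
  d <- runif(6, 60, 140)
  expect_equal(p_dispersion(d)$pwd_ms, p_dispersion(rev(d))$pwd_ms)
  expect_gte(p_dispersion(d)$pwd_ms, 0)
})

test_that("heart rate is 60 over the mean interval", {
  expect_equal(heart_rate(rep(1, 5))$bpm, 60)
  expect_identical(heart_rate(rep(0.6818, 10))$bpm_int, 88L)
  expect_identical(heart_rate(rep(2, 10), "RR")$bpm_int, 30L)
  expect_true(is.na(heart_rate(numeric(0))$bpm))
  expect_error(heart_rate(c(1, -1)), "positive")
  # homogeneity: scaling intervals by c divides the rate by c
  iv <- c(0.8, 0.82, 0.78)
  expect_equal(heart_rate(3 * iv)$bpm_int, heart_rate(iv)$bpm_int %/% 3)
  expect_equal(60 / heart_rate(2 * iv)$mean_interval_s,
    (60 / heart_rate(iv)$mean_interval_s) / 2,
    tolerance = 1e-12
  )
})

test_that("P amplitude is baseline-corrected and flagged at 0.25 mV", {
  sim <- sim_sinus()
  fid <- fid_of("sinus", sim_sinus)
  bf <- beat_features(sim$record, fid)
  expect_true(all(abs(bf$p_amp_mv - 0.15) < 0.01, na.rm = TRUE))
  expect_true(all(bf$p_amp_normal, na.rm = TRUE))

  # a +1 mV baseline offset must not move the corrected amplitude
  shifted <- sim$record
  shifted$MLII <- shifted$MLII + 1.0
  bf2 <- beat_features(shifted, delineate(shifted))
  expect_true(all(abs(bf2$p_amp_mv - bf$p_amp_mv) < 0.01, na.rm = TRUE))

  # an abnormally tall P is flagged
  tall <- generate_ecg(
    rhythm_script("sinus", atrial_interval = 0.8, duration = 30),
    morphology = beat_morphology("tall_p")
  )
  bft <- beat_features(tall$record, delineate(tall$record))
  expect_true(mean(!bft$p_amp_normal, na.rm = TRUE) > 0.9)
})

test_that("measured PR on noiseless sinus stays within 8 ms of the script", {
  sim <- sim_sinus() # scripted PR 160 ms
  bf <- beat_features(sim$record, fid_of("sinus", sim_sinus))
  expect_lt(abs(mean(bf$pr_ms, na.rm = TRUE) - 160), 8)
  expect_true(mean(bf$pr_normal, na.rm = TRUE) > 0.95)
  expect_true(all(bf$p_dur_ms > 0, na.rm = TRUE))
})

test_that("lead features aggregate rates and multi-lead dispersion", {
  fidd <- fid_of("dissoc", sim_dissoc)
  lf <- lead_features(fidd)
  expect_identical(lf$atrial_bpm, 88L)
  expect_identical(lf$ventricular_bpm, 30L)

  # two leads with scripted width jitter exercise the dispersion flag
  sim <- generate_ecg(rhythm_script("sinus",
    atrial_interval = 0.8, duration = 30,
    n_leads = 2, p_width_jitter = 0.35
  ))
  fids <- lapply(ecg_leads(sim$record), function(l) delineate(sim$record, lead = l))
  lf2 <- lead_features(fids)
  expect_gte(lf2$pwd_ms, 0)
  expect_true(is.finite(lf2$pwd_ms))
})
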