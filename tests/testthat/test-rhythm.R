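# Rule-based rhythm assessment.

test_that("scripted rhythms map to their record labels", {
  a <- classify_rhythm(fid_of("sinus", sim_sinus))
  expect_identical(a$record_label, "sinus")
  expect_true(all(a$beats$label == "normal"))
  expect_identical(a$atrial_bpm, 75L)

  b <- classify_rhythm(fid_of("brady", sim_brady))
  expect_identical(b$record_label, "sinus_bradycardia")
  expect_identical(b$ventricular_bpm, 50L)

  d <- classify_rhythm(fid_of("dissoc", sim_dissoc))
  expect_identical(d$record_label, "av_dissociation")
  expect_gt(d$atrial_bpm, d$ventricular_bpm)
  expect_gt(d$circular_variance, 0.5)

  dr <- classify_rhythm(fid_of("dropped", sim_dropped))
  expect_identical(dr$record_label, "intermittent_block")
  expect_gte(dr$n_nonconducted, 10) # one per 5-beat cycle over 60 s
})

test_that("PAC beats are flagged early with an incomplete compensatory pause", {
  p <- classify_rhythm(fid_of("pac", sim_pac))
  expect_identical(p$record_label, "sinus")
  expect_gte(p$n_pac, 10) # every 8th beat over 90 s
  expect_identical(p$n_nonconducted, 0L)
})

test_that("association separates coupled conduction from dissociation", {
  fs <- 250
  fid_s <- fid_of("sinus", sim_sinus)
  as_s <- associate_pq(fid_s$p_peak, fid_s$qrs_on, fs)
  expect_equal(as_s$match_fraction, 1.0)
  expect_lt(as_s$interval_sd_ms, 20)
  expect_lt(as_s$circular_variance, 0.1)

  fid_d <- fid_of("dissoc", sim_dissoc)
  as_d <- associate_pq(fid_d$p_peak, fid_d$qrs_on, fs)
  expect_gt(as_d$circular_variance, 0.5)
  expect_lt(as_d$match_fraction, 0.9)

  vac <- associate_pq(integer(0), fid_s$qrs_on, fs)
  expect_identical(nrow(vac$match), 0L)
  expect_true(is.na(vac$match_fraction))
})

test_that("records with too few beats are indeterminate", {
  sim <- generate_ecg(rhythm_script("sinus", atrial_interval = 1.0, duration = 4))
  a <- classify_rhythm(delineate(sim$record))
  expect_identical(a$record_label, "indeterminate")
})

test_that("classification is deterministic and carries the dispersion flag", {
  fid <- fid_of("sinus", sim_sinus)
  a1 <- classify_rhythm(fid, pwd_ms = 45)
  a2 <- classify_rhythm(fid, pwd_ms = 45)
  expect_identical(glance(a1), glance(a2))
  expect_true(a1$pwd_flag)
  expect_false(classify_rhythm(fid, pwd_ms = 20)$pwd_flag)
})

test_that("tidiers expose per-beat labels and the record summary", {
  a <- classify_rhythm(fid_of("dropped", sim_dropped))
  td <- tidy(a)
  expect_true(all(c("p_peak", "label") %in% names(td)))
  gl <- glance(a)
  expect_identical(gl$record_label, "intermittent_block")
  expect_identical(gl$n_nonconducted, a$n_nonconducted)
})
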