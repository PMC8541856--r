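# Synthetic generator: analytic beats, rhythm scripts, noise, determinism.

test_that("make_beat places wave peaks at their analytic centers", {
  m <- beat_morphology()
  m$amp[m$wave != "P"] <- 0
  b <- make_beat(m, fs = 250)
  p_row <- b$waves[b$waves$wave == "P", ]
  expect_equal(which.max(b$signal) - 1L, p_row$center)

  m0 <- beat_morphology()
  m0$amp <- rep(0, 5)
  expect_true(all(make_beat(m0, fs = 250)$signal == 0))

  expect_error(make_beat(beat_morphology(), fs = 50), "fs")
  bad <- beat_morphology()
  bad$sigma[2] <- -0.01
  expect_error(make_beat(bad, fs = 250), "positive")
})

test_that("normal-preset P wave stays inside textbook limits", {
  m <- beat_morphology("normal")
  p <- m[m$wave == "P", ]
  expect_lt(p$amp, 0.25)
  # brute-force scan of the sampled P Gaussian at the 1% boundary
  fs <- 1000
  tt <- seq(-0.2, 0.2, by = 1 / fs)
  g <- p$amp * exp(-(tt - 0)^2 / (2 * p$sigma^2))
  support <- range(which(g >= 0.01 * p$amp))
  expect_lt(diff(support) / fs, 0.12)
})

test_that("sinus script lays P waves on the exact scripted lattice", {
  sim <- sim_sinus10()
  p <- sim$truth[sim$truth$wave == "P", ]
  expect_identical(nrow(p), 10L)
  expect_true(all(diff(p$peak) == 250L))
})

test_that("AV dissociation reproduces the 88/30 bpm census", {
  sim <- sim_dissoc()
  n_p <- sum(sim$truth$wave == "P")
  n_qrs <- sum(sim$truth$wave == "QRS")
  expect_lte(abs(n_p - 88), 1)
  expect_lte(abs(n_qrs - 30), 1)
  # rate round-trip to 3 significant figures on the noiseless lattice
  pp <- diff(sim$truth$peak[sim$truth$wave == "P"]) / 250
  expect_equal(signif(60 / mean(pp), 3), signif(60 / 0.6818, 3))
})

test_that("truth respects ordering, bounds and the beat-count invariant", {
  for (sim in list(sim_sinus(), sim_dropped(), sim_pac())) {
    tr <- sim$truth
    expect_true(all(tr$onset <= tr$peak & tr$peak <= tr$offset))
    expect_true(all(tr$onset >= 0 & tr$offset < nrow(sim$record)))
  }
  cases <- list(
    c(ai = 1.0, dur = 10), c(ai = 0.8, dur = 60), c(ai = 1.2, dur = 90)
  )
  for (cs in cases) {
    sim <- generate_ecg(rhythm_script("sinus",
      atrial_interval = cs[["ai"]],
      duration = cs[["dur"]]
    ))
    n_p <- sum(sim$truth$wave == "P")
    expect_lte(abs(n_p - floor(cs[["dur"]] / cs[["ai"]])), 1)
  }
})

test_that("seed fully determines the record; truth ignores the noise seed", {
  sc <- function(seed) {
    rhythm_script("sinus",
      atrial_interval = 0.8, duration = 20,
      noise = noise_spec(snr_db = 20), seed = seed
    )
  }
  a <- generate_ecg(sc(7))
  b <- generate_ecg(sc(7))
  expect_identical(a$record$MLII, b$record$MLII)
  expect_identical(a$truth, b$truth)
  c <- generate_ecg(sc(8))
  expect_identical(a$truth$peak, c$truth$peak)
  expect_false(identical(a$record$MLII, c$record$MLII))
})

test_that("add_noise meets its SNR and variance contracts", {
  sim <- generate_ecg(rhythm_script("sinus", atrial_interval = 0.8, duration = 20))
  expect_identical(add_noise(sim$record, noise_spec(), seed = 1), sim$record)

  noisy <- add_noise(sim$record, noise_spec(snr_db = 20), seed = 3)
  injected <- noisy$MLII - sim$record$MLII
  snr <- 10 * log10(mean(sim$record$MLII^2) / mean(injected^2))
  expect_lt(abs(snr - 20), 0.5)

  flat <- ecg_record(rep(0, 5000), fs = 250)
  noisy0 <- add_noise(flat, noise_spec(gaussian_sd = 0.05), seed = 4)
  expect_lt(abs(var(noisy0$MLII) / 0.05^2 - 1), 0.05)
})

test_that("colliding wave lattices warn instead of failing", {
  expect_warning(
    generate_ecg(rhythm_script("av_dissociation",
      atrial_interval = 0.5, ventricular_interval = 2.0,
      duration = 20, atrial_phase = 0
    )),
    "collision"
  )
})

test_that("scripts validate their parameters", {
  expect_error(rhythm_script("sinus", duration = -1), "duration")
  expect_error(rhythm_script("sinus", fs = 50), "fs")
  expect_error(rhythm_script("sinus", atrial_interval = 0), "positive")
  expect_error(rhythm_script("pac", pac_prematurity = 1.2), "prematurity")
})
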