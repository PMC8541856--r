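# QRS detection and RR intervals.

test_that("noiseless sinus beats are all found with exact R peaks", {
  sim <- sim_sinus10()
  q <- detect_qrs(sim$record)
  tq <- sim$truth[sim$truth$wave == "QRS", ]
  expect_identical(nrow(q), nrow(tq))
  expect_true(all(abs(q$r_peak - tq$peak) <= 1))
  expect_true(all(q$onset < q$r_peak & q$r_peak < q$offset))
})

test_that("a flat-line record yields an empty result with a warning", {
  flat <- ecg_record(rep(0, 2500), fs = 250)
  expect_warning(q <- detect_qrs(flat), "No QRS")
  expect_identical(nrow(q), 0L)
})

test_that("AV dissociation yields the ventricular census, not the atrial one", {
  sim <- sim_dissoc()
  q <- detect_qrs(sim$record)
  expect_lte(abs(nrow(q) - 30), 1)
})

test_that("rr_intervals converts R peaks to seconds", {
  q <- tibble::tibble(
    beat = 1:3, onset = c(0L, 245L, 495L), r_peak = c(5L, 255L, 505L),
    offset = c(20L, 270L, 520L), strength = 1
  )
  attr(q, "fs") <- 250
  class(q) <- c("qrs_tbl", class(q))
  expect_equal(rr_intervals(q), c(1, 1))
  expect_identical(rr_intervals(q[1, ]), numeric(0))
})

test_that("bradycardia RR comes back at the scripted 2.0 s", {
  sim <- generate_ecg(rhythm_script("bradycardia", atrial_interval = 2.0, duration = 60))
  q <- detect_qrs(sim$record)
  expect_lt(abs(mean(rr_intervals(q)) - 2.0), 0.004)
})

test_that("no two detections violate the 200 ms refractory", {
  for (sim in list(sim_sinus(), sim_pac(), sim_dropped())) {
    q <- detect_qrs(sim$record)
    expect_true(all(diff(q$r_peak) >= 0.2 * 250))
  }
})

test_that("records shorter than 2 s are refused", {
  expect_error(detect_qrs(ecg_record(rnorm(300), fs = 250)), "2 s")
})
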