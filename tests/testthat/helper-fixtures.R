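# Shared fixtures: generated once per test run and memoized, so the heavier
# end-to-end delineations are not recomputed across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, fn) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- fn()
  .fixtures[[key]]
}

sim_sinus10 <- function() {
  fixture("sinus10", function() {
    generate_ecg(rhythm_script("sinus", atrial_interval = 1.0, duration = 10))
  })
}

sim_sinus <- function() {
  fixture("sinus", function() {
    generate_ecg(rhythm_script("sinus", atrial_interval = 0.8, duration = 60))
  })
}

sim_brady <- function() {
  fixture("brady", function() {
    generate_ecg(rhythm_script("bradycardia", atrial_interval = 1.2, duration = 90))
  })
}

sim_dissoc <- function() {
  fixture("dissoc", function() {
    suppressWarnings(generate_ecg(rhythm_script("av_dissociation",
      atrial_interval = 0.6818, ventricular_interval = 2.0, duration = 60
    )))
  })
}

sim_dropped <- function() {
  fixture("dropped", function() {
    generate_ecg(rhythm_script("dropped_qrs", atrial_interval = 0.9677, duration = 60))
  })
}

sim_pac <- function() {
  fixture("pac", function() {
    generate_ecg(rhythm_script("pac", atrial_interval = 0.9, duration = 90))
  })
}

fid_of <- function(key, sim_fn) {
  fixture(paste0(key, "_fid"), function() delineate(sim_fn()$record))
}

# exhaustive neighbor-comparison oracle for modulus extrema
oracle_extrema <- function(w, from = 0L, to = length(w) - 1L) {
  idx <- integer(0)
  amp <- numeric(0)
  for (i in seq(2, length(w) - 1L)) {
    if ((w[i] > w[i - 1] && w[i] > w[i + 1] && w[i] > 0) ||
      (w[i] < w[i - 1] && w[i] < w[i + 1] && w[i] < 0)) {
      if ((i - 1L) >= from && (i - 1L) <= to) {
        idx <- c(idx, i - 1L)
        amp <- c(amp, w[i])
      }
    }
  }
  list(index = idx, amplitude = amp)
}

# O(n*m) dynamic-programming oracle for optimal one-to-one event matching
oracle_optimal_matches <- function(d, t, tol) {
  d <- sort(d)
  t <- sort(t)
  n <- length(d)
  m <- length(t)
  f <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best <- max(f[i, j + 1], f[i + 1, j])
      if (abs(d[i] - t[j]) <= tol) best <- max(best, f[i, j] + 1L)
      f[i + 1, j + 1] <- best
    }
  }
  f[n + 1, m + 1]
}
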