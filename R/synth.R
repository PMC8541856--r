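# Annotated synthetic ECG generator.
#
# Beats are sums of five Gaussians (P, Q, R, S, T), which keeps the ground
# truth analytic: every wave's peak is its Gaussian center and its onset and
# offset are the points where the Gaussian falls to 1% of its peak.

# half-support of a Gaussian at 1% of peak
gauss_half_support <- function(sigma) sigma * sqrt(2 * log(100))

#' Beat morphology presets
#'
#' Describes one beat as five Gaussians, one per wave, each with an amplitude
#' (mV), a center offset relative to the R peak (s) and a width (Gaussian
#' sigma, s).  The `"normal"` preset keeps the P wave inside textbook limits
#' (duration < 0.12 s, amplitude < 0.25 mV); `"pac_p"` is a deliberately
#' wider, taller ectopic P used for premature atrial contractions; `"tall_p"`
#' deliberately violates the amplitude limit.
#'
#' @param preset one of `"normal"`, `"pac_p"`, `"tall_p"`.
#' @param pr PR interval in seconds used to place the P center so that the
#'   analytic P onset sits exactly `pr` before the analytic QRS onset.
#' @return tibble with columns `wave`, `amp`, `center`, `sigma`.
#' @examples
#' beat_morphology("normal")
#' @export
beat_morphology <- function(preset = c("normal", "pac_p", "tall_p"), pr = 0.16) {
  preset <- match.arg(preset)
  m <- tibble(
    wave   = c("P", "Q", "R", "S", "T"),
    amp    = c(0.15, -0.08, 1.00, -0.12, 0.30),
    center = c(NA, -0.045, 0.000, 0.045, 0.300),
    sigma  = c(0.018, 0.012, 0.011, 0.013, 0.055)
  )
  if (preset == "pac_p") {
    m$amp[1] <- 0.19
    m$sigma[1] <- 0.024
  } else if (preset == "tall_p") {
    m$amp[1] <- 0.32
    m$sigma[1] <- 0.020
  }
  # place the P so that analytic S_P = analytic S_Q - pr
  qrs <- m[m$wave %in% c("Q", "R", "S"), ]
  s_q <- min(qrs$center - gauss_half_support(qrs$sigma))
  m$center[1] <- s_q - pr + gauss_half_support(m$sigma[1])
  m
}

check_morphology <- function(morphology) {
  need <- c("wave", "amp", "center", "sigma")
  if (!all(need %in% names(morphology))) {
    abort("`morphology` needs columns wave, amp, center, sigma.")
  }
  if (any(!is.finite(morphology$sigma)) || any(morphology$sigma <= 0)) {
    abort("All morphology widths (sigma) must be positive.")
  }
  invisible(morphology)
}

#' Sample a single beat from a morphology
#'
#' Evaluates the sum-of-Gaussians beat on a sample grid covering every wave's
#' 1% support, and returns the waveform together with the analytic sample
#' index of each wave's center, onset and offset.
#'
#' @param morphology a [beat_morphology()] tibble.
#' @param fs sampling rate in Hz (>= 100).
#' @return list with `signal` (numeric vector, mV), `fs`, and `waves`, a
#'   tibble of per-wave analytic `center`, `onset`, `offset` sample indices
#'   (0-based, relative to the start of the segment).
#' @examples
#' b <- make_beat(beat_morphology(), fs = 250)
#' length(b$signal)
#' @export
make_beat <- function(morphology = beat_morphology(), fs = 250) {
  if (!is.numeric(fs) || length(fs) != 1 || fs < 100) {
    abort("`fs` must be a single number >= 100 Hz.")
  }
  check_morphology(morphology)
  hs <- gauss_half_support(morphology$sigma)
  t0 <- min(morphology$center - hs) - 0.02
  t1 <- max(morphology$center + hs) + 0.02
  tt <- seq(t0, t1, by = 1 / fs)
  x <- numeric(length(tt))
  for (i in seq_len(nrow(morphology))) {
    x <- x + morphology$amp[i] *
      exp(-(tt - morphology$center[i])^2 / (2 * morphology$sigma[i]^2))
  }
  waves <- tibble(
    wave   = morphology$wave,
    center = round((morphology$center - t0) * fs),
    onset  = round((morphology$center - hs - t0) * fs),
    offset = round((morphology$center + hs - t0) * fs)
  )
  list(signal = x, fs = fs, waves = waves)
}

#' Noise specification for synthetic records
#'
#' @param snr_db signal-to-noise ratio of the additive Gaussian component in
#'   dB relative to the clean signal power; `Inf` disables it.
#' @param gaussian_sd absolute additive Gaussian standard deviation in mV;
#'   used instead of `snr_db` when the latter is `Inf` or the clean signal
#'   has zero power.
#' @param baseline_amp,baseline_freq baseline-wander sinusoid amplitude (mV)
#'   and frequency (Hz).
#' @param powerline_amp,powerline_freq powerline sinusoid amplitude (mV) and
#'   frequency (Hz).
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(snr_db = Inf, gaussian_sd = 0,
                       baseline_amp = 0, baseline_freq = 0.33,
                       powerline_amp = 0, powerline_freq = 50) {
  if (is.na(snr_db)) abort("`snr_db` must be finite or Inf (disabled).")
  structure(
    list(
      snr_db = snr_db, gaussian_sd = gaussian_sd, baseline_amp = baseline_amp,
      baseline_freq = baseline_freq, powerline_amp = powerline_amp,
      powerline_freq = powerline_freq
    ),
    class = "noise_spec"
  )
}

noise_enabled <- function(spec) {
  is.finite(spec$snr_db) || spec$gaussian_sd > 0 ||
    spec$baseline_amp > 0 || spec$powerline_amp > 0
}

#' Script a synthetic rhythm
#'
#' Declares the rhythm to simulate: wave lattices, conduction pattern, record
#' duration, sampling rate, noise and seed.  The seed fully determines the
#' generated record; the ground truth never depends on the noise.
#'
#' @param kind rhythm kind: `"sinus"`, `"bradycardia"`, `"av_dissociation"`
#'   (independent atrial and ventricular lattices), `"dropped_qrs"`
#'   (the QRS-T after every `drop_every`-th P is omitted), or `"pac"`
#'   (every `pac_every`-th beat is a premature atrial contraction).
#' @param atrial_interval P-P interval of the atrial lattice, seconds.
#' @param ventricular_interval R-R interval of the ventricular lattice,
#'   seconds (AV dissociation only).
#' @param pr_delay PR interval (analytic P onset to QRS onset), seconds.
#' @param pr_delay_pac PR interval of conducted PAC beats, seconds.
#' @param drop_every in `"dropped_qrs"`, every `drop_every`-th P wave is
#'   nonconducted.
#' @param pac_every in `"pac"`, every `pac_every`-th beat is ectopic.
#' @param pac_prematurity fraction by which the PAC coupling interval is
#'   shorter than the base P-P interval; the post-PAC pause is
#'   `2*PP - coupling - 0.1*PP` (an incomplete compensatory pause).
#' @param duration record length in seconds.
#' @param fs sampling rate, Hz (>= 100).
#' @param atrial_phase for AV dissociation, the delay of the first P after
#'   the first R, seconds.  The default keeps the default 88/30 bpm lattice
#'   clear of QRS-T complexes over a 60 s record.
#' @param n_leads number of leads; extra leads are gain-scaled copies with
#'   independent noise.
#' @param p_width_jitter fractional spread of the P-wave width across leads
#'   (exercises P-wave dispersion); 0 keeps all leads identical in width.
#' @param noise a [noise_spec()].
#' @param seed integer seed controlling every random component.
#' @return list of class `rhythm_script`.
#' @export
rhythm_script <- function(kind = c("sinus", "bradycardia", "av_dissociation",
                                   "dropped_qrs", "pac"),
                          atrial_interval = 0.8,
                          ventricular_interval = 2.0,
                          pr_delay = 0.16,
                          pr_delay_pac = 0.18,
                          drop_every = 5L,
                          pac_every = 8L,
                          pac_prematurity = 0.25,
                          duration = 60,
                          fs = 250,
                          atrial_phase = 0.45,
                          n_leads = 1L,
                          p_width_jitter = 0,
                          noise = noise_spec(),
                          seed = 1L) {
  kind <- match.arg(kind)
  if (duration <= 0) abort("`duration` must be positive.")
  if (fs < 100) abort("`fs` must be >= 100 Hz.")
  if (atrial_interval <= 0 || ventricular_interval <= 0 || pr_delay <= 0) {
    abort("Intervals must be positive.")
  }
  if (pac_prematurity <= 0 || pac_prematurity >= 1) {
    abort("`pac_prematurity` must be in (0, 1).")
  }
  structure(
    list(
      kind = kind, atrial_interval = atrial_interval,
      ventricular_interval = ventricular_interval, pr_delay = pr_delay,
      pr_delay_pac = pr_delay_pac, drop_every = as.integer(drop_every),
      pac_every = as.integer(pac_every), pac_prematurity = pac_prematurity,
      duration = duration, fs = fs, atrial_phase = atrial_phase,
      n_leads = as.integer(n_leads), p_width_jitter = p_width_jitter,
      noise = noise, seed = as.integer(seed)
    ),
    class = "rhythm_script"
  )
}

# Build the list of wave instances (absolute center times) for a script.
# Returns a tibble: beat, wave, amp, center (s), sigma, conducted.
schedule_waves <- function(script, morphology, morphology_pac) {
  ai <- script$atrial_interval
  vi <- script$ventricular_interval
  dur <- script$duration
  r_start <- 0.4
  qrs_margin <- 0.55 # room for the trailing T wave
  p_margin <- 0.15

  p_off_from_pr <- function(m, pr) {
    qrs <- m[m$wave %in% c("Q", "R", "S"), ]
    s_q <- min(qrs$center - gauss_half_support(qrs$sigma))
    s_q - pr + gauss_half_support(m$sigma[m$wave == "P"])
  }
  p_off <- p_off_from_pr(morphology, script$pr_delay)

  emit <- function(beat, r_time, m, waves, conducted = TRUE, p_time = NA) {
    rows <- m[m$wave %in% waves, ]
    centers <- r_time + rows$center
    if ("P" %in% waves && !is.na(p_time)) centers[rows$wave == "P"] <- p_time
    tibble(
      beat = beat, wave = rows$wave, amp = rows$amp,
      center = centers, sigma = rows$sigma, conducted = conducted
    )
  }

  out <- list()
  if (script$kind %in% c("sinus", "bradycardia")) {
    r_times <- seq(r_start, dur - qrs_margin, by = ai)
    for (k in seq_along(r_times)) {
      out[[k]] <- emit(k, r_times[k], morphology, c("P", "Q", "R", "S", "T"))
    }
  } else if (script$kind == "av_dissociation") {
    r_times <- seq(r_start, dur - qrs_margin, by = vi)
    p_times <- seq(r_start + script$atrial_phase, dur - p_margin, by = ai)
    for (k in seq_along(r_times)) {
      out[[length(out) + 1]] <- emit(k, r_times[k], morphology, c("Q", "R", "S", "T"))
    }
    for (j in seq_along(p_times)) {
      out[[length(out) + 1]] <- emit(
        length(r_times) + j, p_times[j] - p_off, morphology, "P",
        conducted = FALSE, p_time = p_times[j]
      )
    }
  } else if (script$kind == "dropped_qrs") {
    p_times <- seq(r_start + p_off, dur - qrs_margin + p_off, by = ai)
    for (j in seq_along(p_times)) {
      conducted <- (j %% script$drop_every) != 0L
      waves <- if (conducted) c("P", "Q", "R", "S", "T") else "P"
      out[[j]] <- emit(j, p_times[j] - p_off, morphology, waves,
        conducted = conducted, p_time = p_times[j]
      )
    }
  } else if (script$kind == "pac") {
    p_off_pac <- p_off_from_pr(morphology_pac, script$pr_delay_pac)
    coupling <- (1 - script$pac_prematurity) * ai
    pause <- 2 * ai - coupling - 0.1 * ai
    p_t <- r_start + p_off
    j <- 0L
    while (TRUE) {
      j <- j + 1L
      is_pac <- (j %% script$pac_every) == 0L
      m <- if (is_pac) morphology_pac else morphology
      off <- if (is_pac) p_off_pac else p_off
      r_time <- p_t - off
      if (r_time > dur - qrs_margin) break
      out[[j]] <- emit(j, r_time, m, c("P", "Q", "R", "S", "T"), p_time = p_t)
      p_t <- p_t + if (is_pac) pause else if ((j + 1L) %% script$pac_every == 0L) coupling else ai
    }
  }
  bind_rows(out)
}

# Warn (not error) when waves from different beats collide in time.
warn_collisions <- function(events, tol = 0.04) {
  ev <- events[order(events$center), ]
  if (nrow(ev) < 2) {
    return(invisible(0L))
  }
  dt <- diff(ev$center)
  cross <- ev$beat[-1] != ev$beat[-nrow(ev)]
  n_bad <- sum(dt < tol & cross)
  if (n_bad > 0) {
    warn(sprintf(
      "%d wave collision(s) closer than %.0f ms between different beats; waveform superposes them.",
      n_bad, tol * 1000
    ))
  }
  invisible(n_bad)
}

render_events <- function(events, n, fs) {
  x <- numeric(n)
  for (i in seq_len(nrow(events))) {
    c_i <- events$center[i]
    s_i <- events$sigma[i]
    i0 <- max(0L, floor((c_i - 5 * s_i) * fs))
    i1 <- min(n - 1L, ceiling((c_i + 5 * s_i) * fs))
    if (i1 < i0) next
    idx <- i0:i1
    x[idx + 1L] <- x[idx + 1L] +
      events$amp[i] * exp(-(idx / fs - c_i)^2 / (2 * s_i^2))
  }
  x
}

# run `expr` under a private RNG stream, restoring the caller's state
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate an annotated synthetic ECG record
#'
#' Lays the scripted rhythm's waves on the sample grid, sums their Gaussians,
#' adds the scripted noise, and returns the record together with its exact
#' ground truth.  Identical `(script, morphology)` pairs give bit-identical
#' output; the ground truth never depends on the noise seed.
#'
#' @param script a [rhythm_script()].
#' @param morphology a [beat_morphology()] tibble for normal beats.
#' @param morphology_pac morphology used for ectopic P waves in `"pac"`
#'   scripts.
#' @return list with `record` (an [ecg_record()] tibble) and `truth`, a
#'   tibble of one row per emitted wave: `beat`, `wave` (P/QRS/T), `onset`,
#'   `peak`, `offset` (0-based samples), `time` (s), `conducted`, plus the
#'   `rhythm` label as an attribute.
#' @examples
#' sim <- generate_ecg(rhythm_script("sinus", atrial_interval = 1, duration = 10))
#' sum(sim$truth$wave == "P")
#' @export
generate_ecg <- function(script, morphology = beat_morphology(pr = script$pr_delay),
                         morphology_pac = beat_morphology("pac_p", pr = script$pr_delay_pac)) {
  if (!inherits(script, "rhythm_script")) abort("`script` must be a rhythm_script().")
  check_morphology(morphology)
  fs <- script$fs
  n <- round(script$duration * fs)
  events <- schedule_waves(script, morphology, morphology_pac)
  if (nrow(events) == 0) abort("Script produced no beats; increase `duration`.")
  warn_collisions(events)

  # per-lead width jitter (P waves only), deterministic in the lead index
  jit <- if (script$n_leads > 1) {
    seq(-1, 1, length.out = script$n_leads) * script$p_width_jitter
  } else {
    0
  }
  gains <- c(1, 0.7, 1.15, 0.85, 1.05, 0.9)[seq_len(script$n_leads)]
  gains[is.na(gains)] <- 1
  leads <- matrix(0, nrow = n, ncol = script$n_leads)
  for (l in seq_len(script$n_leads)) {
    ev <- events
    ev$sigma[ev$wave == "P"] <- ev$sigma[ev$wave == "P"] * (1 + jit[l])
    leads[, l] <- gains[l] * render_events(ev, n, fs)
  }
  lead_names <- c("MLII", "V1", "V2", "V5", "I", "II")[seq_len(script$n_leads)]
  rec <- ecg_record(leads, fs,
    leads = lead_names,
    origin = sprintf("synthetic:%s seed=%d", script$kind, script$seed)
  )
  rec <- add_noise(rec, script$noise, seed = script$seed)

  hs <- gauss_half_support(events$sigma)
  per_wave <- tibble(
    beat = events$beat,
    wave = ifelse(events$wave %in% c("Q", "R", "S"), "QRS", events$wave),
    member = events$wave,
    onset = pmax(0L, as.integer(round((events$center - hs) * fs))),
    peak = as.integer(round(events$center * fs)),
    offset = pmin(n - 1L, as.integer(round((events$center + hs) * fs))),
    amp = events$amp,
    conducted = events$conducted
  )
  truth <- per_wave %>%
    group_by(.data$beat, .data$wave) %>%
    summarise(
      onset = min(.data$onset),
      peak = .data$peak[which.max(abs(.data$amp))],
      offset = max(.data$offset),
      conducted = .data$conducted[1],
      .groups = "drop"
    ) %>%
    mutate(time = .data$peak / fs) %>%
    arrange(.data$peak)
  attr(truth, "rhythm") <- script$kind
  attr(truth, "fs") <- fs
  list(record = rec, truth = truth)
}

#' Add scripted noise to an ECG record
#'
#' Adds white Gaussian noise at a requested SNR (dB, relative to the clean
#' signal power of each lead), a baseline-wander sinusoid and a powerline
#' sinusoid.  With noise disabled the record is returned unchanged.
#'
#' @param record an [ecg_record()] tibble (the clean signal).
#' @param spec a [noise_spec()].
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return the noisy record.
#' @export
add_noise <- function(record, spec, seed = 1L) {
  if (!inherits(spec, "noise_spec")) abort("`spec` must be a noise_spec().")
  if (!noise_enabled(spec)) {
    return(record)
  }
  fs <- ecg_fs(record)
  leads <- ecg_leads(record)
  n <- nrow(record)
  tt <- (seq_len(n) - 1) / fs
  with_private_seed(seed, {
    for (ld in leads) {
      x <- record[[ld]]
      p_sig <- mean(x^2)
      sd_n <- if (is.finite(spec$snr_db) && p_sig > 0) {
        sqrt(p_sig / 10^(spec$snr_db / 10))
      } else {
        spec$gaussian_sd
      }
      if (sd_n > 0) x <- x + rnorm(n, sd = sd_n)
      if (spec$baseline_amp > 0) {
        ph <- runif(1, 0, 2 * pi)
        x <- x + spec$baseline_amp * sin(2 * pi * spec$baseline_freq * tt + ph)
      }
      if (spec$powerline_amp > 0) {
        ph <- runif(1, 0, 2 * pi)
        x <- x + spec$powerline_amp * sin(2 * pi * spec$powerline_freq * tt + ph)
      }
      record[[ld]] <- x
    }
  })
  record
}
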