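# Rule-based rhythm assessment over delineated fiducials.  The rules encode
# the classic surface-ECG criteria: a premature atrial contraction is an
# early P of different morphology with PR > 120 ms and an incomplete
# compensatory pause; a nonconducted P has no QRS within the conduction
# window; complete AV dissociation shows no stable P-to-QRS coupling with
# the atrial rate above the ventricular rate.

#' Associate P waves with following QRS complexes
#'
#' Each P is matched to the nearest following QRS onset within the
#' association cap (default 400 ms).  The spread of the resulting intervals
#' distinguishes coupled conduction (tight) from AV dissociation (diffuse):
#' intervals are mapped to phases of the ventricular cycle and summarised by
#' their circular variance (0 = locked, 1 = uniform).
#'
#' @param p_peaks 0-based P-peak samples.
#' @param qrs_on 0-based QRS-onset samples.
#' @param fs sampling rate, Hz.
#' @param config an [ecg_config()].
#' @return list with `match` (tibble of `p_peak`, `qrs_on`, `interval_ms`),
#'   `match_fraction`, `interval_sd_ms`, and `circular_variance` (NA with
#'   fewer than 3 matches).
#' @export
associate_pq <- function(p_peaks, qrs_on, fs, config = ecg_config()) {
  cr <- config$rules
  p_peaks <- sort(p_peaks[!is.na(p_peaks)])
  qrs_on <- sort(qrs_on[!is.na(qrs_on)])
  if (length(p_peaks) == 0 || length(qrs_on) == 0) {
    return(list(
      match = tibble(
        p_peak = integer(), qrs_on = integer(), interval_ms = numeric()
      ),
      match_fraction = NA_real_, interval_sd_ms = NA_real_,
      circular_variance = NA_real_
    ))
  }
  cap <- cr$assoc_max_ms / 1000 * fs
  rows <- lapply(p_peaks, function(p) {
    nxt <- qrs_on[qrs_on > p]
    if (length(nxt) == 0 || nxt[1] - p > cap) {
      return(NULL)
    }
    tibble(p_peak = p, qrs_on = nxt[1], interval_ms = (nxt[1] - p) / fs * 1000)
  })
  m <- bind_rows(rows)
  rr <- if (length(qrs_on) > 1) median(diff(qrs_on)) else NA_real_
  # circular variance over ALL P-to-next-QRS intervals (uncapped): coupling
  # concentrates the phases, dissociation spreads them around the cycle
  cv <- NA_real_
  iv_all <- vapply(p_peaks, function(p) {
    nxt <- qrs_on[qrs_on > p]
    if (length(nxt) == 0) NA_real_ else nxt[1] - p
  }, numeric(1))
  iv_all <- iv_all[!is.na(iv_all)]
  if (length(iv_all) >= 3 && is.finite(rr) && rr > 0) {
    ph <- 2 * pi * (iv_all %% rr) / rr
    cv <- 1 - sqrt(mean(cos(ph))^2 + mean(sin(ph))^2)
  }
  list(
    match = m,
    match_fraction = nrow(m) / length(p_peaks),
    interval_sd_ms = if (nrow(m) >= 2) sd(m$interval_ms) else NA_real_,
    circular_variance = cv
  )
}

#' Rule-based rhythm assessment of a delineated record
#'
#' Labels every beat (`normal`, `PAC`, `nonconducted_P`, `dissociated`) and
#' the whole record (`sinus`, `sinus_bradycardia`, `av_dissociation`,
#' `intermittent_block`, or `indeterminate`), with supporting rates and
#' counts.  All rule thresholds live in the config.  Fewer than five beats
#' give an indeterminate assessment.
#'
#' @param fiducials an `ecg_fiducials` tibble from [delineate()].
#' @param fs sampling rate; defaults to the one stored in `fiducials`.
#' @param pwd_ms optional P-wave dispersion (ms) from [lead_features()] on
#'   a multi-lead record; sets the dispersion flag.
#' @param config an [ecg_config()].
#' @return object of class `rhythm_assessment`: list with `record_label`,
#'   `beats` (per-P tibble), `atrial_bpm`, `ventricular_bpm`,
#'   `n_nonconducted`, `n_pac`, `circular_variance`, `pwd_flag`.
#' @examples
#' sim <- generate_ecg(rhythm_script("sinus", atrial_interval = 0.8, duration = 30))
#' classify_rhythm(delineate(sim$record))$record_label
#' @export
classify_rhythm <- function(fiducials, fs = attr(fiducials, "fs"),
                            pwd_ms = NA_real_, config = ecg_config()) {
  cr <- config$rules
  f <- fiducials
  p <- sort(f$p_peak[!is.na(f$p_peak)])
  q_on <- sort(f$qrs_on[!is.na(f$qrs_on)])
  r <- sort(f$r_peak[!is.na(f$r_peak)])
  rates <- lead_features(fiducials, fs)
  out <- list(
    record_label = "indeterminate",
    beats = tibble(p_peak = p, label = rep("normal", length(p))),
    atrial_bpm = rates$atrial_bpm, ventricular_bpm = rates$ventricular_bpm,
    n_nonconducted = 0L, n_pac = 0L,
    circular_variance = NA_real_,
    pwd_flag = if (is.na(pwd_ms)) NA else pwd_ms >= cr$pwd_ms
  )
  class(out) <- "rhythm_assessment"
  if (length(p) < cr$min_beats || length(r) < 2) {
    return(out)
  }

  assoc <- associate_pq(p, q_on, fs, config)
  out$circular_variance <- assoc$circular_variance

  # per-beat labels
  cond_win <- cr$conduction_ms / 1000 * fs
  labels <- rep("normal", length(p))
  pp <- diff(p)
  med_pp <- median(pp)
  for (k in seq_along(p)) {
    has_qrs <- any(q_on > p[k] & q_on - p[k] <= cond_win)
    if (!has_qrs) {
      labels[k] <- "nonconducted_P"
      next
    }
    if (k >= 2 && k < length(p)) {
      coupling <- p[k] - p[k - 1]
      pause <- p[k + 1] - p[k]
      premature <- coupling <= (1 - cr$pac_prematurity) * med_pp
      # incomplete compensatory pause: the two cycles around the ectopic P
      # sum to less than twice the basic cycle length
      incomplete <- pause > med_pp && (coupling + pause) < 2 * med_pp
      pr_ok <- TRUE
      nxt <- q_on[q_on > p[k]]
      p_on_k <- f$p_on[match(p[k], f$p_peak)]
      if (length(nxt) > 0 && !is.na(p_on_k)) {
        pr_ok <- (nxt[1] - p_on_k) / fs * 1000 > cr$pac_pr_min_ms
      }
      if (premature && incomplete && pr_ok) labels[k] <- "PAC"
    }
  }

  dissociated <- !is.na(assoc$circular_variance) &&
    assoc$circular_variance > cr$circ_var_min &&
    !is.na(out$atrial_bpm) && !is.na(out$ventricular_bpm) &&
    out$atrial_bpm > out$ventricular_bpm
  if (dissociated) labels[labels %in% c("normal", "nonconducted_P")] <- "dissociated"

  out$beats$label <- labels
  out$n_nonconducted <- sum(labels == "nonconducted_P")
  out$n_pac <- sum(labels == "PAC")

  one_to_one <- !is.na(assoc$match_fraction) && assoc$match_fraction >= 0.9 &&
    out$n_nonconducted == 0
  out$record_label <- if (dissociated) {
    "av_dissociation"
  } else if (out$n_nonconducted > 0) {
    "intermittent_block"
  } else if (one_to_one && !is.na(out$ventricular_bpm) &&
    out$ventricular_bpm < cr$brady_bpm) {
    "sinus_bradycardia"
  } else if (one_to_one) {
    "sinus"
  } else {
    "indeterminate"
  }
  out
}

#' @export
print.rhythm_assessment <- function(x, ...) {
  cat(sprintf(
    "Rhythm: %s (atrial %s bpm, ventricular %s bpm)\n  beats: %d P (%d PAC, %d nonconducted); circular variance %s\n",
    x$record_label, x$atrial_bpm, x$ventricular_bpm, nrow(x$beats),
    x$n_pac, x$n_nonconducted,
    ifelse(is.na(x$circular_variance), "NA", sprintf("%.2f", x$circular_variance))
  ))
  invisible(x)
}
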