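# P-wave characteristic parameters with textbook normal-range flags:
# PR interval 120-200 ms, P duration < 120 ms, P amplitude < 0.25 mV,
# P-wave dispersion < 40 ms (>= 50 ms suggesting heterogeneous atrial
# conduction).  All intervals are reported in milliseconds, amplitudes
# in mV; sample indices are 0-based throughout.

#' PR interval in milliseconds
#'
#' Time from P-wave onset `S_P` to QRS onset `S_Q`, flagged normal when
#' inside the inclusive 120-200 ms range.
#'
#' @param s_q,s_p 0-based sample indices of QRS onset and P onset
#'   (vectorized).
#' @param fs sampling rate, Hz.
#' @return tibble with `pr_ms` and `pr_normal`.
#' @examples
#' pr_interval(540, 500, 250) # 160 ms, normal
#' @export
pr_interval <- function(s_q, s_p, fs) {
  if (any(s_q <= s_p)) abort("QRS onset must come after P onset (S_Q > S_P).")
  ms <- (s_q - s_p) / fs * 1000
  tibble(pr_ms = ms, pr_normal = ms >= 120 & ms <= 200)
}

#' P-wave duration in milliseconds
#'
#' Width from P onset `S_P` to P offset `E_P`, flagged normal when strictly
#' below 120 ms.
#'
#' @param s_p,e_p 0-based sample indices of P onset and offset (vectorized).
#' @param fs sampling rate, Hz.
#' @return tibble with `p_dur_ms` and `p_dur_normal`.
#' @export
p_duration <- function(s_p, e_p, fs) {
  if (any(e_p <= s_p)) abort("P offset must come after P onset (E_P > S_P).")
  ms <- (e_p - s_p) / fs * 1000
  tibble(p_dur_ms = ms, p_dur_normal = ms < 120)
}

#' P-wave dispersion across leads
#'
#' Difference between the longest (`Pm`) and shortest (`Pn`) P-wave duration
#' measured in different leads of the same recording; < 40 ms is normal and
#' >= 50 ms suggests heterogeneous atrial electrical activity.
#'
#' @param durations numeric vector of per-lead P durations in ms (>= 2
#'   leads).
#' @return tibble with `pm_ms`, `pn_ms`, `pwd_ms`, `pwd_normal`,
#'   `pwd_heterogeneous`.
#' @examples
#' p_dispersion(c(110, 95, 80))
#' @export
p_dispersion <- function(durations) {
  durations <- durations[!is.na(durations)]
  if (length(durations) < 2) {
    abort("P-wave dispersion needs measured durations from at least 2 leads.")
  }
  pwd <- max(durations) - min(durations)
  tibble(
    pm_ms = max(durations), pn_ms = min(durations), pwd_ms = pwd,
    pwd_normal = pwd < 40, pwd_heterogeneous = pwd >= 50
  )
}

#' Heart rate from PP or RR intervals
#'
#' `HR = 60 / mean(interval)`, reported both to 0.1 bpm and as a rounded
#' integer.
#'
#' @param intervals numeric vector of intervals in seconds (all > 0).
#' @param kind `"PP"` (atrial rate) or `"RR"` (ventricular rate).
#' @return tibble with `kind`, `mean_interval_s`, `bpm`, `bpm_int`; with no
#'   intervals a one-row tibble of NAs.
#' @examples
#' heart_rate(rep(0.6818, 10))$bpm_int # 88
#' @export
heart_rate <- function(intervals, kind = c("PP", "RR")) {
  kind <- match.arg(kind)
  intervals <- intervals[!is.na(intervals)]
  if (length(intervals) == 0) {
    return(tibble(
      kind = kind, mean_interval_s = NA_real_, bpm = NA_real_,
      bpm_int = NA_integer_
    ))
  }
  if (any(intervals <= 0)) abort("All intervals must be positive.")
  m <- mean(intervals)
  tibble(
    kind = kind, mean_interval_s = m,
    bpm = round(60 / m, 1), bpm_int = as.integer(round(60 / m))
  )
}

#' P-wave amplitude with baseline correction
#'
#' Peak voltage minus the median of an isoelectric PR-segment window 40-10
#' ms before the QRS onset; flagged normal when strictly below 0.25 mV.
#' Without a usable baseline window the raw peak voltage is returned and
#' flagged approximate.
#'
#' @param record an [ecg_record()].
#' @param p_peak 0-based P-peak sample.
#' @param qrs_on 0-based QRS-onset sample of the same beat (NA for a
#'   nonconducted P).
#' @param lead lead name or index.
#' @return tibble with `p_amp_mv`, `p_amp_normal`, `baseline_corrected`.
#' @export
p_amplitude <- function(record, p_peak, qrs_on = NA, lead = 1L) {
  fs <- ecg_fs(record)
  x <- lead_signal(record, lead)
  if (any(p_peak < 0 | p_peak >= length(x))) abort("P peak outside record.")
  one <- function(pk, qo) {
    base <- NA_real_
    if (!is.na(qo)) {
      lo <- qo - round(0.04 * fs)
      hi <- qo - round(0.01 * fs)
      if (lo >= 0 && hi > lo) base <- median(x[(lo + 1L):(hi + 1L)])
    }
    corrected <- !is.na(base)
    amp <- x[pk + 1L] - if (corrected) base else 0
    tibble(
      p_amp_mv = amp, p_amp_normal = abs(amp) < 0.25,
      baseline_corrected = corrected
    )
  }
  bind_rows(Map(one, p_peak, qrs_on))
}

#' Per-beat P-wave features of a delineated record
#'
#' Computes PR interval, P duration and baseline-corrected P amplitude for
#' every beat with the needed fiducials, with normal-range flags.
#'
#' @param record the [ecg_record()] that was delineated.
#' @param fiducials an `ecg_fiducials` tibble from [delineate()].
#' @param lead lead name or index (the one that was delineated).
#' @return tibble with one row per beat: `beat`, `p_peak`, `pr_ms`,
#'   `pr_normal`, `p_dur_ms`, `p_dur_normal`, `p_amp_mv`, `p_amp_normal`.
#' @export
beat_features <- function(record, fiducials, lead = attr(fiducials, "lead")) {
  fs <- ecg_fs(record)
  f <- fiducials
  pr <- rep(NA_real_, nrow(f))
  prn <- rep(NA, nrow(f))
  ok <- !is.na(f$p_on) & !is.na(f$qrs_on) & f$qrs_on > f$p_on
  if (any(ok)) {
    v <- pr_interval(f$qrs_on[ok], f$p_on[ok], fs)
    pr[ok] <- v$pr_ms
    prn[ok] <- v$pr_normal
  }
  dur <- rep(NA_real_, nrow(f))
  durn <- rep(NA, nrow(f))
  ok <- !is.na(f$p_on) & !is.na(f$p_off) & f$p_off > f$p_on
  if (any(ok)) {
    v <- p_duration(f$p_on[ok], f$p_off[ok], fs)
    dur[ok] <- v$p_dur_ms
    durn[ok] <- v$p_dur_normal
  }
  amp <- rep(NA_real_, nrow(f))
  ampn <- rep(NA, nrow(f))
  ok <- !is.na(f$p_peak)
  if (any(ok)) {
    v <- p_amplitude(record, f$p_peak[ok], f$qrs_on[ok], lead)
    amp[ok] <- v$p_amp_mv
    ampn[ok] <- v$p_amp_normal
  }
  tibble(
    beat = f$beat, p_peak = f$p_peak,
    pr_ms = pr, pr_normal = prn,
    p_dur_ms = dur, p_dur_normal = durn,
    p_amp_mv = amp, p_amp_normal = ampn
  )
}

#' Record-level rates and multi-lead P-wave dispersion
#'
#' Summarises a delineation (or several, one per lead) into atrial and
#' ventricular rates and, with two or more leads, the P-wave dispersion.
#'
#' @param fiducials one `ecg_fiducials` tibble or a named list of them (one
#'   per lead).
#' @param fs sampling rate; defaults to the one stored in the fiducials.
#' @return one-row tibble: `mean_pp_s`, `mean_rr_s`, `atrial_bpm`,
#'   `ventricular_bpm` (integer bpm), and when possible `pwd_ms` with its
#'   flags.
#' @export
lead_features <- function(fiducials, fs = NULL) {
  flist <- if (inherits(fiducials, "ecg_fiducials")) list(fiducials) else fiducials
  if (is.null(fs)) fs <- attr(flist[[1]], "fs")
  f1 <- flist[[1]]
  pp <- diff(sort(f1$p_peak[!is.na(f1$p_peak)])) / fs
  rr <- diff(sort(f1$r_peak[!is.na(f1$r_peak)])) / fs
  at <- heart_rate(pp, "PP")
  vt <- heart_rate(rr, "RR")
  out <- tibble(
    n_p = sum(!is.na(f1$p_peak)), n_qrs = sum(!is.na(f1$r_peak)),
    mean_pp_s = at$mean_interval_s, mean_rr_s = vt$mean_interval_s,
    atrial_bpm = at$bpm_int, ventricular_bpm = vt$bpm_int
  )
  if (length(flist) >= 2) {
    durs <- vapply(flist, function(f) {
      ok <- !is.na(f$p_on) & !is.na(f$p_off) & f$p_off > f$p_on
      if (!any(ok)) {
        return(NA_real_)
      }
      mean((f$p_off[ok] - f$p_on[ok]) / fs * 1000)
    }, numeric(1))
    if (sum(!is.na(durs)) >= 2) {
      out <- dplyr::bind_cols(out, p_dispersion(durs))
    }
  }
  out
}
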