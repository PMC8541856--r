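# P-wave (and T-wave) delineation.  After QRS anchoring, modulus-extremum
# pairs of the P-scale coefficients inside a pre-QRS search segment are
# screened by two adaptive amplitude thresholds and a 100 ms pairing window;
# the zero crossing between an accepted pair localizes the P peak.  A
# secondary whole-record scan over the QRS-T-cancelled signal recovers
# nonconducted P waves (dropped QRS, AV dissociation) that have no
# anchoring complex of their own.

#' P-wave search segment ahead of a QRS complex
#'
#' The segment spans `[S_Q - min(0.45 s, 0.9 x preceding RR), S_Q - 0.03 s]`
#' and is clipped at the previous QRS offset.  A non-positive span means no
#' P can be looked for ahead of this beat.
#'
#' @param qrs a `qrs_tbl` from [detect_qrs()].
#' @param i beat number (row of `qrs`).
#' @param fs sampling rate, Hz.
#' @param config an [ecg_config()].
#' @param prev_t_off optional T offset of the preceding beat; at short RR
#'   the segment is clipped behind it so the previous T cannot pose as a P.
#' @return list with `start`, `end` (0-based samples), `beat`, and
#'   `degenerate` (TRUE when the segment has no usable span).
#' @export
search_segment <- function(qrs, i, fs = attr(qrs, "fs"), config = ecg_config(),
                           prev_t_off = NA) {
  if (i < 1 || i > nrow(qrs)) abort("No such QRS complex.")
  cs <- config$segment
  s_q <- qrs$onset[i]
  pre <- if (i > 1) {
    min(cs$pre_max_s, cs$rr_frac * (qrs$r_peak[i] - qrs$r_peak[i - 1]) / fs)
  } else {
    cs$pre_max_s
  }
  start <- s_q - floor(pre * fs)
  if (i > 1) start <- max(start, qrs$offset[i - 1] + 1L)
  if (!is.na(prev_t_off)) start <- max(start, as.integer(prev_t_off) + 1L)
  start <- max(start, 0L)
  end <- s_q - floor(cs$pre_end_s * fs)
  # a span too short to hold an extremum pair is as good as empty
  list(
    start = as.integer(start), end = as.integer(end), beat = i,
    degenerate = (end - start) < floor(0.04 * fs)
  )
}

#' Adaptive amplitude thresholds for extremum-pair screening
#'
#' The positive gate is `px_factor` (default 2/5) times the mean of the (up
#' to) ten largest positive extremum amplitudes in the search segment; the
#' negative gate is `py_factor` (default 1/3) times the mean of the ten most
#' negative.  With no positive (negative) extrema the corresponding gate is
#' a sentinel that rejects every pair.
#'
#' @param extrema tibble from [find_extrema()].
#' @param config an [ecg_config()].
#' @return list with `px` (> 0) and `py` (< 0), possibly `Inf`/`-Inf`
#'   sentinels.
#' @export
p_thresholds <- function(extrema, config = ecg_config()) {
  cp <- config$pwave
  pos <- extrema$amplitude[extrema$amplitude > 0]
  neg <- extrema$amplitude[extrema$amplitude < 0]
  px <- if (length(pos) == 0) {
    Inf
  } else {
    cp$px_factor * mean(sort(pos, decreasing = TRUE)[seq_len(min(cp$top_k, length(pos)))])
  }
  py <- if (length(neg) == 0) {
    -Inf
  } else {
    cp$py_factor * mean(sort(neg)[seq_len(min(cp$top_k, length(neg)))])
  }
  list(px = px, py = py)
}

#' Screen modulus-extremum pairs for P-wave candidacy
#'
#' Walks the index-sorted extrema earliest first and accepts an adjacent
#' maximum-then-minimum pair when the positive member exceeds `px`, the
#' negative member is below `py`, and the two are closer than 100 ms; each
#' extremum is used at most once.  Minimum-first adjacencies straddle a
#' valley, not a crest, and are skipped.
#'
#' @param extrema tibble from [find_extrema()], sorted by index.
#' @param thresholds list from [p_thresholds()].
#' @param fs sampling rate, Hz.
#' @param config an [ecg_config()].
#' @return tibble with one row per accepted pair: `a_idx`, `a_amp` (positive
#'   member), `b_idx`, `b_amp` (negative member), `interval_ms`, `slope`
#'   (amplitude difference per ms) and `strength` (`|A| + |B|`).
#' @export
screen_pairs <- function(extrema, thresholds, fs, config = ecg_config()) {
  cp <- config$pwave
  max_gap <- cp$pair_max_ms / 1000 * fs
  empty <- tibble(
    a_idx = integer(), a_amp = numeric(), b_idx = integer(),
    b_amp = numeric(), interval_ms = numeric(), slope = numeric(),
    strength = numeric()
  )
  if (nrow(extrema) < 2) {
    return(empty)
  }
  # only extrema passing their amplitude gate can form pairs; sub-gate
  # ripples between a pair's members must not break its adjacency
  extrema <- extrema[extrema$amplitude > thresholds$px |
    extrema$amplitude < thresholds$py, ]
  if (nrow(extrema) < 2) {
    return(empty)
  }
  extrema <- extrema[order(extrema$index), ]
  out <- list()
  i <- 1L
  while (i < nrow(extrema)) {
    a1 <- extrema$amplitude[i]
    a2 <- extrema$amplitude[i + 1L]
    dt <- extrema$index[i + 1L] - extrema$index[i]
    pos <- i
    neg <- i + 1L
    # an upright wave's signature is maximum-then-minimum (downward zero
    # crossing at the crest); minimum-first pairs straddle a valley and are
    # skipped without consuming either extremum
    if (a1 > 0 && a2 < 0 && dt < max_gap) {
      dt_ms <- (extrema$index[neg] - extrema$index[pos]) / fs * 1000
      out[[length(out) + 1L]] <- tibble(
        a_idx = extrema$index[pos], a_amp = extrema$amplitude[pos],
        b_idx = extrema$index[neg], b_amp = extrema$amplitude[neg],
        interval_ms = abs(dt_ms),
        slope = (extrema$amplitude[pos] - extrema$amplitude[neg]) / dt_ms,
        strength = extrema$amplitude[pos] - extrema$amplitude[neg]
      )
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  res <- if (length(out) == 0) empty else bind_rows(out)
  if (cp$slope_min > 0) res <- res[abs(res$slope) >= cp$slope_min, ]
  res
}

#' Slope of a modulus-extremum pair
#'
#' Signed amplitude difference of the pair divided by its time difference,
#' in coefficient units per millisecond.
#'
#' @param amp_a,amp_b signed amplitudes of the two extrema.
#' @param t_a,t_b their times in milliseconds.
#' @return the slope `K`.
#' @export
pair_slope <- function(amp_a, amp_b, t_a, t_b) {
  if (any(t_a == t_b)) abort("Extremum pair has zero time difference.")
  (amp_a - amp_b) / (t_a - t_b)
}

# localize one P (or T) from screened pairs: largest pair wins
locate_wave <- function(pairs, w, fs, boundary_frac, boundary_max_ms) {
  if (nrow(pairs) == 0) {
    return(NULL)
  }
  best <- pairs[which.max(pairs$strength), ]
  peak <- tryCatch(
    zero_crossing(w, best$a_idx, best$b_idx),
    error = function(e) NA_integer_
  )
  if (is.na(peak)) {
    return(NULL)
  }
  cap <- round(boundary_max_ms / 1000 * fs)
  left <- min(best$a_idx, best$b_idx)
  right <- max(best$a_idx, best$b_idx)
  onset <- decay_left(w, left, boundary_frac * abs(w[left + 1L]), cap)
  offset <- decay_right(w, right, boundary_frac * abs(w[right + 1L]), cap)
  list(
    onset = as.integer(onset), peak = as.integer(peak),
    offset = as.integer(offset), strength = best$strength
  )
}

#' Locate the P wave inside one search segment
#'
#' Applies [p_thresholds()] and [screen_pairs()] to the P-scale extrema of
#' the segment and localizes at most one P wave: the zero crossing of the
#' strongest accepted pair.  Onset and offset are the samples where the
#' coefficient magnitude first falls below 5% of the pair's extremum
#' amplitudes, searching outward.
#'
#' @param wt an [ecg_wavelet()] of the lead.
#' @param segment list from [search_segment()].
#' @param fs sampling rate, Hz.
#' @param config an [ecg_config()].
#' @return list with `onset`, `peak`, `offset`, `strength`, or `NULL` when
#'   no pair is accepted (absent P).
#' @export
locate_p <- function(wt, segment, fs, config = ecg_config()) {
  if (segment$degenerate) {
    return(NULL)
  }
  j <- config$wavelet$p_scale
  ex <- find_extrema(wt, j, segment$start, segment$end)
  thr <- p_thresholds(ex, config)
  pairs <- screen_pairs(ex, thr, fs, config)
  locate_wave(
    pairs, wt$w[[j]], fs,
    config$pwave$boundary_frac, config$pwave$boundary_max_ms
  )
}

#' Locate the T wave after one QRS complex
#'
#' Same pair-screening machinery applied in a post-QRS window
#' `[QRS offset + 0.08 s, QRS offset + min(0.4 s, 0.6 x RR)]`.
#'
#' @param wt an [ecg_wavelet()] of the lead.
#' @param qrs a `qrs_tbl`.
#' @param i beat number.
#' @param fs sampling rate, Hz.
#' @param config an [ecg_config()].
#' @return list with `peak` and `offset`, or `NULL` (absent T).
#' @export
locate_t <- function(wt, qrs, i, fs = attr(qrs, "fs"), config = ecg_config()) {
  ct <- config$twave
  rr <- if (i < nrow(qrs)) {
    (qrs$r_peak[i + 1] - qrs$r_peak[i]) / fs
  } else if (i > 1) {
    (qrs$r_peak[i] - qrs$r_peak[i - 1]) / fs
  } else {
    ct$max_s / ct$rr_frac
  }
  start <- qrs$offset[i] + round(ct$after_qrs_s * fs)
  end <- qrs$offset[i] + round(min(ct$max_s, ct$rr_frac * rr) * fs)
  end <- min(end, wt$n - 1L)
  if (start >= end) {
    return(NULL)
  }
  j <- config$wavelet$p_scale
  ex <- find_extrema(wt, j, start, end)
  thr <- p_thresholds(ex, config)
  cfg_t <- config
  cfg_t$pwave$pair_max_ms <- ct$pair_max_ms
  pairs <- screen_pairs(ex, thr, fs, cfg_t)
  res <- locate_wave(
    pairs, wt$w[[j]], fs,
    config$pwave$boundary_frac, config$pwave$boundary_max_ms
  )
  if (is.null(res)) {
    return(NULL)
  }
  list(peak = res$peak, offset = res$offset, strength = res$strength)
}

# Average-beat QRS-T cancellation: subtract the mean beat (window around
# each detected R, cosine-tapered) from the signal, aligning each beat by
# best integer lag, so atrial activity hidden in QRS-T becomes visible to
# the secondary scan.
cancel_qrst <- function(x, r_peaks, fs) {
  n <- length(x)
  w0 <- -round(0.15 * fs)
  w1 <- round(0.50 * fs) # past the T offset but short of the next beat's P
  win <- w0:w1
  usable <- r_peaks[r_peaks + w0 >= 0 & r_peaks + w1 <= n - 1L]
  if (length(usable) < 3) {
    return(x)
  }
  edge_base <- function(seg) {
    k <- min(8L, length(seg))
    median(c(seg[seq_len(k)], seg[seq(length(seg) - k + 1L, length(seg))]))
  }
  beats <- vapply(usable, function(r) {
    seg <- x[r + win + 1L]
    # the window edges are isoelectric; anchoring there keeps the template
    # baseline at zero and makes cancellation offset-invariant
    seg - edge_base(seg)
  }, numeric(length(win)))
  # per-sample median across beats: robust to the minority of windows a
  # neighbouring ectopic or dissociated P wave strays into
  tpl <- apply(beats, 1, median)
  taper_n <- round(0.03 * fs)
  taper <- rep(1, length(win))
  ramp <- (1 - cos(pi * seq_len(taper_n) / taper_n)) / 2
  taper[seq_len(taper_n)] <- ramp
  taper[length(taper) - seq_len(taper_n) + 1L] <- ramp
  tpl <- tpl * taper
  # subtract at the best integer lag, then refine by a fractional shift of
  # the template (linear interpolation): sub-sample jitter between beats
  # otherwise leaves derivative-sized residual spikes at the R peak
  ks <- seq_along(tpl)
  shifted_tpl <- function(f) {
    if (f == 0) {
      return(tpl)
    }
    stats::approx(ks, tpl, xout = ks - f, rule = 2)$y
  }
  xc <- x
  for (r in usable) {
    lags <- -3:3
    sse <- vapply(lags, function(l) {
      idx <- r + l + win + 1L
      if (idx[1] < 1 || idx[length(idx)] > n) {
        return(Inf)
      }
      seg <- x[idx]
      sum((seg - edge_base(seg) - tpl)^2)
    }, numeric(1))
    l <- lags[which.min(sse)]
    idx <- r + l + win + 1L
    idx_ok <- idx >= 1 & idx <= n
    seg <- x[idx[idx_ok]]
    seg <- seg - edge_base(seg)
    best <- tpl[idx_ok]
    best_sse <- sum((seg - best)^2)
    for (f in c(-0.5, -0.25, 0.25, 0.5)) {
      cand_tpl <- shifted_tpl(f)[idx_ok]
      s <- sum((seg - cand_tpl)^2)
      if (s < best_sse) {
        best <- cand_tpl
        best_sse <- s
      }
    }
    xc[idx[idx_ok]] <- xc[idx[idx_ok]] - best
  }
  xc
}

# Signal-domain boundary refinement.  The wavelet 5% decay points bracket
# the wave generously (the scale-4 response is much wider than the wave
# itself); inside the bracket the onset/offset are re-placed where the
# baseline-corrected signal amplitude falls below `frac` of the peak
# amplitude (floored at 3x the high-frequency noise level) for `run`
# consecutive samples.
refine_wave_bounds <- function(x, peak, lo, hi, frac, noise_sd, run = 2L) {
  n <- length(x)
  lo <- max(0L, lo)
  hi <- min(n - 1L, hi)
  if (is.na(peak) || peak < lo || peak > hi || hi - lo < 4L) {
    return(list(onset = lo, offset = hi))
  }
  seg <- x[(lo + 1L):(hi + 1L)]
  line <- seg[1] + (seg[length(seg)] - seg[1]) *
    (seq_along(seg) - 1) / (length(seg) - 1)
  d <- abs(seg - line)
  pk <- peak - lo + 1L
  thr <- max(frac * d[pk], 3 * noise_sd)
  below_run <- function(idx_seq) {
    cnt <- 0L
    for (i in idx_seq) {
      cnt <- if (d[i] < thr) cnt + 1L else 0L
      if (cnt >= run) {
        # report the first sub-threshold sample of the run (nearest the peak)
        return(i - sign(idx_seq[length(idx_seq)] - idx_seq[1]) * (run - 1L))
      }
    }
    idx_seq[length(idx_seq)]
  }
  on_i <- if (pk > 1) below_run(seq(pk - 1L, 1L)) else 1L
  off_i <- if (pk < length(d)) below_run(seq(pk + 1L, length(d))) else length(d)
  list(onset = lo + on_i - 1L, offset = lo + off_i - 1L)
}

# high-frequency noise level estimate (robust, insensitive to waves)
estimate_noise_sd <- function(x) {
  stats::mad(diff(x)) / sqrt(2)
}

# linear detrend of a short segment
detrend_seg <- function(y) {
  n <- length(y)
  t <- seq_len(n) - (n + 1) / 2
  y - mean(y) - sum(y * t) / sum(t^2) * t
}

# normalized correlation of a candidate segment with the P template,
# maximized over small lags
p_template_corr <- function(x, peak, tpl, half, max_lag = 3L) {
  n <- length(x)
  best <- -1
  for (l in -max_lag:max_lag) {
    lo <- peak + l - half
    hi <- peak + l + half
    if (lo < 0 || hi > n - 1L) next
    seg <- detrend_seg(x[(lo + 1L):(hi + 1L)])
    den <- sqrt(sum(seg^2) * sum(tpl^2))
    if (den == 0) next
    best <- max(best, sum(seg * tpl) / den)
  }
  best
}

#' Delineate a full record: QRS, P and T fiducials per beat
#'
#' Runs the whole pipeline on one lead: QRS detection, per-beat P search
#' ahead of each QRS, T location behind it, and a secondary whole-record P
#' scan on the QRS-T-cancelled signal that recovers P waves with no
#' anchoring QRS (nonconducted beats, AV dissociation).  Secondary
#' candidates must resemble the primary P waves in pair strength, may not
#' fall within the merge window of a primary P, and respect a P refractory.
#'
#' @param record an [ecg_record()] tibble.
#' @param lead lead name or index.
#' @param config an [ecg_config()].
#' @return tibble of class `ecg_fiducials`, one row per beat (or lone P):
#'   0-based sample columns `p_on`, `p_peak`, `p_off`, `qrs_on`, `r_peak`,
#'   `qrs_off`, `t_peak`, `t_off` (NA when absent), `p_strength`, and
#'   `source` (`"primary"`, `"secondary"`, or `"qrs_only"`).
#' @examples
#' sim <- generate_ecg(rhythm_script("sinus", atrial_interval = 1, duration = 10))
#' fid <- delineate(sim$record)
#' sum(!is.na(fid$p_peak))
#' @export
delineate <- function(record, lead = 1L, config = ecg_config()) {
  fs <- ecg_fs(record)
  x <- lead_signal(record, lead)
  if (length(x) == 0) {
    return(empty_fiducials(fs, lead))
  }
  wt <- ecg_wavelet(x, config$wavelet$max_scale)
  qrs <- withCallingHandlers(
    detect_qrs(record, lead, config, wt),
    warning = function(w) invokeRestart("muffleWarning")
  )
  cp <- config$pwave

  rows <- list()
  p_peaks <- integer(0)
  p_strengths <- numeric(0)
  for (i in seq_len(nrow(qrs))) {
    prev_t_off <- if (i > 1 && !is.na(rows[[i - 1]]$t_off)) rows[[i - 1]]$t_off else NA
    seg <- search_segment(qrs, i, fs, config, prev_t_off = prev_t_off)
    p <- locate_p(wt, seg, fs, config)
    t <- locate_t(wt, qrs, i, fs, config)
    rows[[i]] <- tibble(
      p_on = if (is.null(p)) NA_integer_ else p$onset,
      p_peak = if (is.null(p)) NA_integer_ else p$peak,
      p_off = if (is.null(p)) NA_integer_ else p$offset,
      qrs_on = qrs$onset[i], r_peak = qrs$r_peak[i], qrs_off = qrs$offset[i],
      t_peak = if (is.null(t)) NA_integer_ else t$peak,
      t_off = if (is.null(t)) NA_integer_ else t$offset,
      p_strength = if (is.null(p)) NA_real_ else p$strength,
      source = if (is.null(p)) "qrs_only" else "primary"
    )
    if (!is.null(p)) {
      p_peaks <- c(p_peaks, p$peak)
      p_strengths <- c(p_strengths, p$strength)
    }
  }

  # record-level consistency gate: a segment-relative threshold pair can
  # pass in a segment holding no P at all, so candidates much weaker than
  # the record's P population are demoted to absent-P
  demote <- function(i) {
    rows[[i]]$p_on <<- NA_integer_
    rows[[i]]$p_peak <<- NA_integer_
    rows[[i]]$p_off <<- NA_integer_
    rows[[i]]$p_strength <<- NA_real_
    rows[[i]]$source <<- "qrs_only"
  }
  refresh <- function() {
    kept <- vapply(rows, function(r) !is.na(r$p_strength), logical(1))
    p_peaks <<- vapply(rows[kept], function(r) r$p_peak, integer(1))
    p_strengths <<- vapply(rows[kept], function(r) r$p_strength, numeric(1))
  }
  if (length(p_strengths) >= cp$secondary_min_primary) {
    floor_str <- cp$secondary_gate * median(p_strengths)
    weak <- which(vapply(
      rows,
      function(r) !is.na(r$p_strength) && r$p_strength < floor_str,
      logical(1)
    ))
    if (length(weak) > 0) {
      for (i in weak) demote(i)
      refresh()
    }
  }

  # P-template verification: the record's own average P (detrended) must
  # correlate with every reported candidate, suppressing noise pairs that
  # slip past the amplitude thresholds
  p_tpl <- NULL
  half <- round(cp$corr_half_ms / 1000 * fs)
  if (length(p_peaks) >= cp$corr_min_primary) {
    segs <- lapply(p_peaks, function(p) {
      if (p - half < 0 || p + half > length(x) - 1L) {
        return(NULL)
      }
      detrend_seg(x[(p - half + 1L):(p + half + 1L)])
    })
    segs <- segs[!vapply(segs, is.null, logical(1))]
    if (length(segs) >= cp$corr_min_primary) {
      p_tpl <- rowMeans(do.call(cbind, segs))
      bad <- which(vapply(rows, function(r) {
        !is.na(r$p_peak) &&
          p_template_corr(x, r$p_peak, p_tpl, half) < cp$corr_min
      }, logical(1)))
      if (length(bad) > 0) {
        for (i in bad) demote(i)
        refresh()
      }
    }
  }

  # secondary scan over the cancelled signal
  xc <- if (nrow(qrs) >= 3) cancel_qrst(x, qrs$r_peak, fs) else x
  sec <- secondary_p_scan(xc, qrs, p_peaks, p_strengths, fs, config,
    p_tpl = p_tpl, tpl_half = half
  )

  # signal-domain boundary refinement: P bounds on the cancelled signal,
  # QRS onset on the reconstructed (noise-free) template contribution
  if (isTRUE(cp$refine)) {
    nsd <- estimate_noise_sd(xc)
    qsig <- x - xc
    rows <- c(rows, if (nrow(sec) > 0) lapply(seq_len(nrow(sec)), function(k) sec[k, ]) else NULL)
    for (i in seq_along(rows)) {
      r <- rows[[i]]
      if (!is.na(r$p_peak)) {
        b <- refine_wave_bounds(
          xc, r$p_peak, r$p_on, r$p_off, cp$refine_frac, nsd
        )
        rows[[i]]$p_on <- as.integer(b$onset)
        rows[[i]]$p_off <- as.integer(b$offset)
      }
      if (!is.na(r$r_peak)) {
        rows[[i]]$qrs_on <- refine_qrs_onset(
          qsig, x, r$r_peak, r$qrs_on, cp$qrs_refine_frac, fs
        )
      }
    }
    out <- bind_rows(rows)
  } else {
    out <- bind_rows(c(rows, list(sec)))
  }
  if (nrow(out) > 0) {
    ord <- order(ifelse(is.na(out$p_peak), out$r_peak, out$p_peak))
    out <- out[ord, ]
    out$beat <- seq_len(nrow(out))
    out <- out[, c("beat", setdiff(names(out), "beat"))]
  } else {
    out <- empty_fiducials(fs, lead)
  }
  attr(out, "fs") <- fs
  attr(out, "lead") <- lead
  class(out) <- c("ecg_fiducials", class(out))
  out
}

empty_fiducials <- function(fs, lead) {
  out <- tibble(
    beat = integer(), p_on = integer(), p_peak = integer(), p_off = integer(),
    qrs_on = integer(), r_peak = integer(), qrs_off = integer(),
    t_peak = integer(), t_off = integer(), p_strength = numeric(),
    source = character()
  )
  attr(out, "fs") <- fs
  attr(out, "lead") <- lead
  class(out) <- c("ecg_fiducials", class(out))
  out
}

# QRS onset: leftward search on the reconstructed template contribution
# (exactly zero away from QRS-T), falling back to the raw signal when no
# template was subtracted at this beat
refine_qrs_onset <- function(qsig, x, r_peak, fallback, frac, fs, run = 3L) {
  sig <- qsig
  if (r_peak + 1L > length(sig) || abs(sig[r_peak + 1L]) < 1e-12) sig <- x
  thr <- frac * abs(sig[r_peak + 1L])
  if (thr == 0) {
    return(fallback)
  }
  lo <- max(0L, r_peak - round(0.15 * fs))
  cnt <- 0L
  for (i in seq(r_peak - 1L, lo)) {
    cnt <- if (abs(sig[i + 1L]) < thr) cnt + 1L else 0L
    if (cnt >= run) {
      return(as.integer(i + run - 1L))
    }
  }
  fallback
}

secondary_p_scan <- function(xc, qrs, p_peaks, p_strengths, fs, config,
                             p_tpl = NULL, tpl_half = NULL) {
  cp <- config$pwave
  none <- tibble(
    p_on = integer(), p_peak = integer(), p_off = integer(),
    qrs_on = integer(), r_peak = integer(), qrs_off = integer(),
    t_peak = integer(), t_off = integer(), p_strength = numeric(),
    source = character()
  )
  n <- length(xc)
  wc <- tryCatch(ecg_wavelet(xc, config$wavelet$p_scale), error = function(e) NULL)
  if (is.null(wc)) {
    return(none)
  }
  j <- config$wavelet$p_scale
  # segments bounded by R peaks, overlapping left so no pair is split
  bounds <- if (nrow(qrs) == 0) {
    list(c(0L, n - 1L))
  } else {
    r <- qrs$r_peak
    segs <- list(c(0L, r[1]))
    if (length(r) > 1) {
      for (i in seq_len(length(r) - 1L)) {
        segs[[length(segs) + 1L]] <- c(r[i] - round(0.15 * fs), r[i + 1L])
      }
    }
    segs[[length(segs) + 1L]] <- c(r[length(r)] - round(0.15 * fs), n - 1L)
    segs
  }
  cand <- list()
  for (b in bounds) {
    ex <- find_extrema(wc, j, max(0L, b[1]), min(n - 1L, b[2]))
    thr <- p_thresholds(ex, config)
    pairs <- screen_pairs(ex, thr, fs, config)
    for (k in seq_len(nrow(pairs))) {
      res <- locate_wave(
        pairs[k, ], wc$w[[j]], fs,
        cp$boundary_frac, cp$boundary_max_ms
      )
      if (!is.null(res)) cand[[length(cand) + 1L]] <- as_tibble(res)
    }
  }
  cand <- bind_rows(cand)
  if (nrow(cand) == 0) {
    return(none)
  }
  cand <- cand[!duplicated(cand$peak), ]
  # consistency gate against the primary P population
  if (length(p_strengths) >= cp$secondary_min_primary) {
    cand <- cand[cand$strength >= cp$secondary_gate * median(p_strengths), ]
  }
  if (nrow(cand) == 0) {
    return(none)
  }
  # template verification on the cancelled signal; unanchored candidates
  # face a stricter gate than anchored ones, which rejects the residual
  # spikes QRS-T cancellation can leave at the R peak
  if (!is.null(p_tpl)) {
    ok <- vapply(cand$peak, function(p) {
      p_template_corr(xc, p, p_tpl, tpl_half) >= cp$corr_min_secondary
    }, logical(1))
    cand <- cand[ok, ]
  }
  if (nrow(cand) == 0) {
    return(none)
  }
  # drop duplicates of primary P waves
  if (length(p_peaks) > 0) {
    merge_n <- round(cp$merge_ms / 1000 * fs)
    keep <- vapply(cand$peak, function(p) all(abs(p - p_peaks) > merge_n), logical(1))
    cand <- cand[keep, ]
  }
  if (nrow(cand) == 0) {
    return(none)
  }
  # P refractory among secondary candidates: keep the stronger
  cand <- cand[order(cand$peak), ]
  refr <- round(cp$p_refractory_ms / 1000 * fs)
  names(cand)[names(cand) == "peak"] <- "zc"
  cand <- enforce_refractory(cand, refr)
  names(cand)[names(cand) == "zc"] <- "peak"
  tibble(
    p_on = cand$onset, p_peak = cand$peak, p_off = cand$offset,
    qrs_on = NA_integer_, r_peak = NA_integer_, qrs_off = NA_integer_,
    t_peak = NA_integer_, t_off = NA_integer_,
    p_strength = cand$strength, source = "secondary"
  )
}
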