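# QRS detection with cross-scale wavelet modulus-maxima evidence.  The QRS
# complex is broadband: its extremum pairs co-occur at scales 2^1-2^3, which
# separates it from the smoother P and T waves, whose fine-scale content is
# negligible.

# centered running RMS over a window of `wn` samples (edges clipped)
running_rms <- function(w, wn) {
  n <- length(w)
  cs <- cumsum(c(0, w^2))
  half <- wn %/% 2
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) - 1L + half + 1L)
  sqrt((cs[hi + 1L] - cs[lo + 1L]) / (hi - lo))
}

# suprathreshold extrema of one scale; thr is a per-sample vector
supra_extrema <- function(wt, scale, thr) {
  ex <- find_extrema(wt, scale)
  ex[abs(ex$amplitude) > thr[ex$index + 1L], ]
}

# strongest-first pairing of adjacent opposite-sign extrema; each extremum
# is used at most once, so side lobes cannot steal a dominant pair's member
pair_adjacent <- function(ex, max_gap) {
  if (nrow(ex) < 2) {
    return(tibble(
      i_first = integer(), amp_first = numeric(),
      i_second = integer(), amp_second = numeric()
    ))
  }
  i <- seq_len(nrow(ex) - 1L)
  ok <- sign(ex$amplitude[i]) != sign(ex$amplitude[i + 1L]) &
    (ex$index[i + 1L] - ex$index[i]) < max_gap
  cand <- i[ok]
  strength <- abs(ex$amplitude[cand]) + abs(ex$amplitude[cand + 1L])
  cand <- cand[order(-strength)]
  used <- logical(nrow(ex))
  keep <- integer(0)
  for (k in cand) {
    if (!used[k] && !used[k + 1L]) {
      keep <- c(keep, k)
      used[c(k, k + 1L)] <- TRUE
    }
  }
  keep <- sort(keep)
  tibble(
    i_first = ex$index[keep], amp_first = ex$amplitude[keep],
    i_second = ex$index[keep + 1L], amp_second = ex$amplitude[keep + 1L]
  )
}

#' Detect QRS complexes in one lead
#'
#' Candidate QRS complexes are opposite-sign modulus-extremum pairs of the
#' scale-2 wavelet coefficients above an adaptive threshold (a fraction of
#' the running RMS), confirmed by suprathreshold extrema at scales 1 and 3
#' near the pair's zero crossing and by a scale-1/scale-2 sharpness ratio.
#' The R peak is the pair's zero crossing snapped to the nearest signal
#' extremum; onset and offset are where the scale-2 coefficient magnitude
#' decays below a fraction of the pair amplitude.  A 200 ms refractory is
#' enforced and RR gaps longer than 1.66 x the median RR are re-scanned at
#' half threshold (search-back).
#'
#' @param record an [ecg_record()] tibble.
#' @param lead lead name or index.
#' @param config an [ecg_config()].
#' @param wt optional precomputed [ecg_wavelet()] of the lead.
#' @return tibble of class `qrs_tbl`: `beat`, `onset`, `r_peak`, `offset`
#'   (0-based samples), `strength`; empty (with a warning) when nothing is
#'   found.
#' @export
detect_qrs <- function(record, lead = 1L, config = ecg_config(), wt = NULL) {
  fs <- ecg_fs(record)
  x <- lead_signal(record, lead)
  if (length(x) < 2 * fs) abort("Record must be at least 2 s long for QRS detection.")
  if (is.null(wt)) wt <- ecg_wavelet(x, config$wavelet$max_scale)
  cq <- config$qrs
  wn <- round(cq$rms_window_s * fs)
  thr <- lapply(config$wavelet$qrs_scales, function(j) {
    cq$rms_factor * running_rms(wt$w[[j]], wn)
  })
  names(thr) <- as.character(config$wavelet$qrs_scales)

  scan <- function(from, to, factor = 1) {
    ex2 <- supra_extrema(wt, 2L, factor * thr[["2"]])
    ex2 <- ex2[ex2$index >= from & ex2$index <= to, ]
    if (nrow(ex2) < 2) {
      return(NULL)
    }
    ex1 <- supra_extrema(wt, 1L, factor * thr[["1"]])
    ex3 <- supra_extrema(wt, 3L, factor * thr[["3"]])
    win <- round(cq$cross_scale_ms / 1000 * fs)
    pairs <- pair_adjacent(ex2, round(cq$pair_max_ms / 1000 * fs))
    if (is.null(pairs) || nrow(pairs) == 0) {
      return(NULL)
    }
    keep <- logical(nrow(pairs))
    zc <- integer(nrow(pairs))
    sharp <- numeric(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      z <- tryCatch(
        zero_crossing(wt, pairs$i_first[k], pairs$i_second[k], 2L),
        error = function(e) NA_integer_
      )
      if (is.na(z)) next
      near1 <- ex1[abs(ex1$index - z) <= win, ]
      near3 <- ex3[abs(ex3$index - z) <= win, ]
      if (nrow(near1) == 0 || nrow(near3) == 0) next
      s2 <- max(abs(pairs$amp_first[k]), abs(pairs$amp_second[k]))
      s1 <- max(abs(near1$amplitude))
      if (s1 < cq$sharpness_min * s2) next
      keep[k] <- TRUE
      zc[k] <- z
      sharp[k] <- s1 / s2
    }
    if (!any(keep)) {
      return(NULL)
    }
    tibble(
      zc = zc[keep],
      a_idx = pairs$i_first[keep], a_amp = pairs$amp_first[keep],
      b_idx = pairs$i_second[keep], b_amp = pairs$amp_second[keep],
      strength = abs(pairs$amp_first[keep]) + abs(pairs$amp_second[keep])
    )
  }

  cand <- scan(0L, wt$n - 1L)
  refr <- round(cq$refractory_ms / 1000 * fs)
  cand <- enforce_refractory(cand, refr)
  # record-level amplitude gate: QRS pairs are an order of magnitude
  # stronger than P/T pairs at scale 2, so smooth waves surviving the
  # adaptive threshold in QRS-free stretches are rejected here
  if (!is.null(cand) && nrow(cand) > 1) {
    ref <- median(sort(cand$strength, decreasing = TRUE)[seq_len(min(10L, nrow(cand)))])
    cand <- cand[cand$strength >= cq$amp_gate * ref, ]
  }
  # search-back in long RR gaps at half threshold
  if (!is.null(cand) && nrow(cand) >= 3) {
    med_rr <- median(diff(cand$zc))
    gaps <- which(diff(cand$zc) > cq$searchback_factor * med_rr)
    extra <- list()
    for (g in gaps) {
      lo <- cand$zc[g] + refr
      hi <- cand$zc[g + 1L] - refr
      if (hi > lo) extra[[length(extra) + 1L]] <- scan(lo, hi, factor = 0.5)
    }
    extra <- bind_rows(extra)
    if (nrow(extra) > 0) {
      ref <- median(sort(cand$strength, decreasing = TRUE)[seq_len(min(10L, nrow(cand)))])
      extra <- extra[extra$strength >= cq$amp_gate * ref, ]
      if (nrow(extra) > 0) cand <- enforce_refractory(bind_rows(cand, extra), refr)
    }
  }
  if (is.null(cand) || nrow(cand) == 0) {
    warn("No QRS complexes found.")
    return(empty_qrs(fs, lead))
  }

  # R snap to the dominant signal deflection near the zero crossing
  snap <- round(cq$snap_ms / 1000 * fs)
  r_peak <- vapply(cand$zc, function(z) {
    lo <- max(0L, z - snap)
    hi <- min(wt$n - 1L, z + snap)
    seg <- x[(lo + 1L):(hi + 1L)]
    seg <- abs(seg - median(seg)) # offset-invariant deflection
    as.integer(lo + which.max(seg) - 1L)
  }, integer(1))

  w2 <- wt$w[[2L]]
  cap <- round(cq$boundary_max_ms / 1000 * fs)
  onset <- mapply(function(i0, amp) {
    decay_left(w2, i0, cq$boundary_frac * abs(amp), cap)
  }, cand$a_idx, cand$a_amp)
  offset <- mapply(function(i0, amp) {
    decay_right(w2, i0, cq$boundary_frac * abs(amp), cap)
  }, cand$b_idx, cand$b_amp)

  ord <- order(r_peak)
  out <- tibble(
    beat = seq_along(ord),
    onset = as.integer(onset[ord]),
    r_peak = as.integer(r_peak[ord]),
    offset = as.integer(offset[ord]),
    strength = cand$strength[ord]
  )
  attr(out, "fs") <- fs
  attr(out, "lead") <- lead
  class(out) <- c("qrs_tbl", class(out))
  out
}

empty_qrs <- function(fs, lead) {
  out <- tibble(
    beat = integer(), onset = integer(), r_peak = integer(),
    offset = integer(), strength = numeric()
  )
  attr(out, "fs") <- fs
  attr(out, "lead") <- lead
  class(out) <- c("qrs_tbl", class(out))
  out
}

# keep the stronger of any two candidates closer than `refr` samples
enforce_refractory <- function(cand, refr) {
  if (is.null(cand) || nrow(cand) < 2) {
    return(cand)
  }
  cand <- cand[order(cand$zc), ]
  keep <- rep(TRUE, nrow(cand))
  last <- 1L
  for (k in 2:nrow(cand)) {
    if (cand$zc[k] - cand$zc[last] < refr) {
      if (cand$strength[k] > cand$strength[last]) {
        keep[last] <- FALSE
        last <- k
      } else {
        keep[k] <- FALSE
      }
    } else {
      last <- k
    }
  }
  cand[keep, ]
}

# first sample left of i0 where |w| < thr (0-based i0), capped
decay_left <- function(w, i0, thr, cap) {
  lo <- max(0L, i0 - cap)
  i <- i0
  while (i > lo && abs(w[i + 1L]) >= thr) i <- i - 1L
  i
}

decay_right <- function(w, i0, thr, cap) {
  hi <- min(length(w) - 1L, i0 + cap)
  i <- i0
  while (i < hi && abs(w[i + 1L]) >= thr) i <- i + 1L
  i
}

#' RR intervals of detected QRS complexes
#'
#' @param qrs a `qrs_tbl` from [detect_qrs()].
#' @param fs sampling rate; defaults to the one stored in `qrs`.
#' @return numeric vector of successive R-R intervals in seconds (empty with
#'   fewer than two complexes).
#' @export
rr_intervals <- function(qrs, fs = attr(qrs, "fs")) {
  if (is.null(fs)) abort("Provide `fs` or a qrs_tbl carrying one.")
  if (nrow(qrs) < 2) {
    return(numeric(0))
  }
  diff(qrs$r_peak) / fs
}
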