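# Detector scoring against ground truth: greedy one-to-one matching within
# a tolerance window, and the Er / Se / Pp summary percentages.

#' Match detected events to ground-truth events
#'
#' Greedy one-to-one matching: candidate (detected, truth) pairs within the
#' tolerance are taken in order of increasing time error, each event used at
#' most once.  Unmatched detections count as false positives, unmatched
#' truths as false negatives.
#'
#' @param detected numeric vector of detected event samples (or times).
#' @param truth numeric vector of true event samples (same units).
#' @param tol tolerance in the same units (e.g. samples); must be > 0.
#' @return list with `tp`, `fp`, `fn` and a `pairs` tibble of matched
#'   `(detected, truth, error)` rows.
#' @examples
#' match_events(c(10, 52, 95), c(10, 50, 90, 130), tol = 5)$tp
#' @export
match_events <- function(detected, truth, tol) {
  if (!is.numeric(tol) || length(tol) != 1 || tol <= 0) {
    abort("`tol` must be a single positive number.")
  }
  detected <- sort(as.numeric(detected))
  truth <- sort(as.numeric(truth))
  nd <- length(detected)
  nt <- length(truth)
  if (nd == 0 || nt == 0) {
    return(list(
      tp = 0L, fp = nd, fn = nt,
      pairs = tibble(detected = numeric(), truth = numeric(), error = numeric())
    ))
  }
  cand <- expand.grid(d = seq_len(nd), t = seq_len(nt))
  cand$err <- abs(detected[cand$d] - truth[cand$t])
  cand <- cand[cand$err <= tol, ]
  cand <- cand[order(cand$err), ]
  used_d <- logical(nd)
  used_t <- logical(nt)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_d[cand$d[k]] && !used_t[cand$t[k]]) {
      keep[k] <- TRUE
      used_d[cand$d[k]] <- TRUE
      used_t[cand$t[k]] <- TRUE
    }
  }
  cand <- cand[keep, ]
  list(
    tp = nrow(cand), fp = nd - nrow(cand), fn = nt - nrow(cand),
    pairs = tibble(
      detected = detected[cand$d], truth = truth[cand$t], error = cand$err
    )
  )
}

#' Detection score: sensitivity, positive predictivity, error rate
#'
#' `Se = 100 TP / (TP + FN)`, `Pp = 100 TP / (TP + FP)`, and the failed
#' detection rate `Er = 100 (FP + FN) / (TP + FN)` (denominator switchable
#' to `TP + FP + FN` via the config).
#'
#' @param tp,fp,fn counts.
#' @param tolerance_ms matching tolerance recorded with the score.
#' @param wave which wave was scored (annotation label).
#' @param config an [ecg_config()].
#' @return object of class `detection_score`.
#' @examples
#' detection_score(99, 2, 1)$se
#' @export
detection_score <- function(tp, fp, fn, tolerance_ms = 75, wave = "P",
                            config = ecg_config()) {
  if (tp + fn == 0) abort("Undefined sensitivity: no true events (TP + FN = 0).")
  er_den <- switch(config$eval$er_denominator,
    tp_fn = tp + fn,
    tp_fp_fn = tp + fp + fn,
    abort("Unknown `er_denominator`.")
  )
  structure(
    list(
      tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
      se = 100 * tp / (tp + fn),
      pp = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
      er = 100 * (fp + fn) / er_den,
      tolerance_ms = tolerance_ms, wave = wave
    ),
    class = "detection_score"
  )
}

#' @export
print.detection_score <- function(x, ...) {
  cat(sprintf(
    "%s-wave detection (tolerance %g ms): TP %d, FP %d, FN %d\n  Se %.2f%%  Pp %.2f%%  Er %.2f%%\n",
    x$wave, x$tolerance_ms, x$tp, x$fp, x$fn, x$se, x$pp, x$er
  ))
  invisible(x)
}

#' Score a delineation against generator ground truth
#'
#' Matches detected peaks of one wave kind to the true peaks at a
#' millisecond tolerance and returns the [detection_score()].
#'
#' @param fiducials an `ecg_fiducials` tibble from [delineate()].
#' @param truth generator truth tibble (from [generate_ecg()]).
#' @param wave `"P"`, `"QRS"` or `"T"`.
#' @param tol_ms matching tolerance in milliseconds.
#' @param fs sampling rate; defaults to the one stored in `fiducials`.
#' @param config an [ecg_config()].
#' @return a `detection_score`.
#' @export
score_detection <- function(fiducials, truth, wave = "P",
                            tol_ms = ecg_config()$eval$tol_ms,
                            fs = attr(fiducials, "fs"),
                            config = ecg_config()) {
  det <- switch(wave,
    P = fiducials$p_peak,
    QRS = fiducials$r_peak,
    T = fiducials$t_peak,
    abort("`wave` must be one of P, QRS, T.")
  )
  det <- det[!is.na(det)]
  tru <- truth$peak[truth$wave == wave]
  m <- match_events(det, tru, tol = tol_ms / 1000 * fs)
  detection_score(m$tp, m$fp, m$fn, tolerance_ms = tol_ms, wave = wave, config = config)
}

#' Study sample-size utilities
#'
#' `sample_size_total()` gives the total sample size
#' `N = Z^2 P (1 - P) / E^2` for estimating a proportion `P` with margin of
#' error `E`; `sample_size_group()` gives the per-group size
#' `n = Z^2 sigma^2 / d^2` for a mean with sampling-error range `d`.  Both
#' round up, with a floor of one.
#'
#' @param z standard-normal quantile (1.96 for 95% confidence).
#' @param p anticipated proportion, in (0, 1).
#' @param e margin of error (> 0).
#' @param sigma anticipated standard deviation (> 0).
#' @param d sampling-error range (> 0).
#' @return integer sample size.
#' @examples
#' sample_size_total(1.96, 0.5, 0.155) # 40
#' sample_size_group(1.96, 0.5, 0.31) # 10
#' @export
sample_size_total <- function(z, p, e) {
  if (z <= 0 || e <= 0 || p <= 0 || p >= 1) {
    abort("Need z > 0, e > 0 and p in (0, 1).")
  }
  max(1L, as.integer(ceiling(z^2 * p * (1 - p) / e^2)))
}

#' @rdname sample_size_total
#' @export
sample_size_group <- function(z, sigma, d) {
  if (z <= 0 || sigma <= 0 || d <= 0) abort("All inputs must be positive.")
  max(1L, as.integer(ceiling(z^2 * sigma^2 / d^2)))
}
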