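# broom-style tidiers for the package's result objects.

#' Tidy a detection score
#'
#' @param x a [detection_score()].
#' @param ... unused.
#' @return long tibble of `(metric, value)` rows: the counts and the three
#'   percentages.
#' @export
tidy.detection_score <- function(x, ...) {
  tibble(
    metric = c("tp", "fp", "fn", "se", "pp", "er"),
    value = c(x$tp, x$fp, x$fn, x$se, x$pp, x$er)
  )
}

#' @rdname tidy.detection_score
#' @return `glance()` returns a one-row tibble with `tp`, `fp`, `fn`, `se`,
#'   `pp`, `er`, `tolerance_ms` and `wave`.
#' @export
glance.detection_score <- function(x, ...) {
  tibble(
    tp = x$tp, fp = x$fp, fn = x$fn, se = x$se, pp = x$pp, er = x$er,
    tolerance_ms = x$tolerance_ms, wave = x$wave
  )
}

#' Tidy a rhythm assessment
#'
#' @param x a [classify_rhythm()] result.
#' @param ... unused.
#' @return `tidy()` the per-beat label tibble; `glance()` a one-row record
#'   summary.
#' @export
tidy.rhythm_assessment <- function(x, ...) {
  x$beats
}

#' @rdname tidy.rhythm_assessment
#' @export
glance.rhythm_assessment <- function(x, ...) {
  tibble(
    record_label = x$record_label,
    atrial_bpm = x$atrial_bpm, ventricular_bpm = x$ventricular_bpm,
    n_beats = nrow(x$beats), n_pac = x$n_pac,
    n_nonconducted = x$n_nonconducted,
    circular_variance = x$circular_variance, pwd_flag = x$pwd_flag
  )
}
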