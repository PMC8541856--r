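# ggplot2 graphics for records, delineations and scores.

#' Plot an ECG record
#'
#' Voltage traces against time, one facet per lead, optionally overlaid
#' with delineated fiducials.
#'
#' @param object an [ecg_record()] tibble.
#' @param fiducials optional `ecg_fiducials` tibble from [delineate()].
#' @param from,to optional time window in seconds.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ecg_tbl <- function(object, fiducials = NULL, from = NULL, to = NULL, ...) {
  fs <- ecg_fs(object)
  leads <- ecg_leads(object)
  long <- tidyr::pivot_longer(
    as_tibble(object), dplyr::all_of(leads),
    names_to = "lead", values_to = "mv"
  )
  long$time <- long$sample / fs
  if (!is.null(from)) long <- long[long$time >= from, ]
  if (!is.null(to)) long <- long[long$time <= to, ]
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~lead, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "voltage (mV)") +
    ggplot2::theme_minimal()
  if (!is.null(fiducials)) {
    marks <- tidyr::pivot_longer(
      as_tibble(fiducials)[, c("beat", "p_peak", "r_peak", "t_peak")],
      c("p_peak", "r_peak", "t_peak"),
      names_to = "wave", values_to = "sample"
    )
    marks <- marks[!is.na(marks$sample), ]
    marks$time <- marks$sample / fs
    marks$wave <- toupper(substr(marks$wave, 1, 1))
    if (!is.null(from)) marks <- marks[marks$time >= from, ]
    if (!is.null(to)) marks <- marks[marks$time <= to, ]
    p <- p + ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$time, colour = .data$wave),
      alpha = 0.5, linetype = "dashed"
    ) +
      ggplot2::labs(colour = "wave")
  }
  p
}

#' Plot a delineation over its record
#'
#' Convenience wrapper around [autoplot.ecg_tbl()].
#'
#' @param record an [ecg_record()].
#' @param fiducials an `ecg_fiducials` tibble.
#' @param ... passed to [autoplot.ecg_tbl()].
#' @return a ggplot object.
#' @export
plot_delineation <- function(record, fiducials, ...) {
  autoplot(record, fiducials = fiducials, ...)
}

#' Plot a detection score
#'
#' Bar chart of sensitivity, positive predictivity and error rate.
#'
#' @param object a [detection_score()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.detection_score <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$metric %in% c("se", "pp", "er"), ]
  d$metric <- factor(toupper(d$metric), levels = c("SE", "PP", "ER"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(width = 0.6, fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f%%", .data$value)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(
      x = NULL, y = "percent",
      title = sprintf("%s-wave detection (+/- %g ms)", object$wave, object$tolerance_ms)
    ) +
    ggplot2::theme_minimal()
}
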