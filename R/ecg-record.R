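#' Build an ECG record tibble
#'
#' An ECG record is a tibble with a 0-based `sample` column and one column of
#' voltages (mV) per lead, carrying the sampling rate as an attribute.  All
#' delineation functions in the package take this tibble as their first
#' argument, so calls chain with the pipe.
#'
#' @param samples numeric matrix or data frame of voltages in mV, one column
#'   per lead, or a bare numeric vector for a single lead.
#' @param fs sampling rate in Hz (> 0).
#' @param leads character vector of lead names; defaults to column names or
#'   `MLII`, `V1`, ... when absent.
#' @param origin free-text provenance note stored with the record.
#' @return A tibble of class `ecg_tbl` with columns `sample` and one per lead.
#' @examples
#' rec <- ecg_record(sin(seq(0, 2 * pi, length.out = 250)), fs = 250)
#' ecg_fs(rec)
#' @export
ecg_record <- function(samples, fs, leads = NULL, origin = "in-memory") {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, ncol = 1)
  }
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) abort("`samples` must be numeric.")
  if (anyNA(samples)) {
    bad <- which(rowSums(is.na(samples)) > 0)[1]
    abort(sprintf("`samples` contains NA/NaN values (first at row %d); refusing to impute.", bad))
  }
  if (is.null(leads)) {
    leads <- colnames(samples)
    if (is.null(leads)) {
      leads <- if (ncol(samples) == 1) "MLII" else paste0("V", seq_len(ncol(samples)))
    }
  }
  if (length(leads) != ncol(samples)) {
    abort("`leads` must name every column of `samples`.")
  }
  out <- as_tibble(as.data.frame(samples), .name_repair = "minimal")
  names(out) <- leads
  out <- tibble(sample = seq_len(nrow(samples)) - 1L) %>% dplyr::bind_cols(out)
  attr(out, "fs") <- as.numeric(fs)
  attr(out, "leads") <- leads
  attr(out, "origin") <- origin
  class(out) <- c("ecg_tbl", class(out))
  out
}

#' Sampling rate, lead names and duration of an ECG record
#'
#' @param record an `ecg_tbl` (or any tibble with an `fs` attribute).
#' @return `ecg_fs()` the sampling rate in Hz; `ecg_leads()` the lead names;
#'   `ecg_duration()` the record length in seconds.
#' @export
ecg_fs <- function(record) {
  fs <- attr(record, "fs")
  if (is.null(fs)) abort("Record has no `fs` attribute; build it with `ecg_record()`.")
  fs
}

#' @rdname ecg_fs
#' @export
ecg_leads <- function(record) {
  leads <- attr(record, "leads")
  if (is.null(leads)) leads <- setdiff(names(record), "sample")
  leads
}

#' @rdname ecg_fs
#' @export
ecg_duration <- function(record) nrow(record) / ecg_fs(record)

# Extract one lead as a bare numeric vector.
lead_signal <- function(record, lead = 1L) {
  leads <- ecg_leads(record)
  if (is.numeric(lead)) lead <- leads[lead]
  if (is.na(lead) || !lead %in% leads) {
    abort(sprintf("Unknown lead; available: %s", paste(leads, collapse = ", ")))
  }
  as.numeric(record[[lead]])
}

#' @export
print.ecg_tbl <- function(x, ...) {
  cat(sprintf(
    "# ECG record: %d samples, %g Hz (%.1f s), leads: %s\n",
    nrow(x), ecg_fs(x), ecg_duration(x), paste(ecg_leads(x), collapse = ", ")
  ))
  NextMethod()
}
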