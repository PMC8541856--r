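# Plain-text ECG and annotation formats.
#
# Record CSV dialect: first line "# fs=<Hz>", second line comma-separated
# lead names, then one comma-separated row of voltages (mV) per sample.
# Annotation TSV: header "sample<TAB>label<TAB>lead", one event per row,
# 0-based sample indices.

ANNOTATION_LABELS <- c(
  "P", "Pon", "Poff", "QRSon", "R", "QRSoff", "T", "Toff", "beat"
)

#' Write and read ECG records as plain-text CSV
#'
#' @param record an [ecg_record()] tibble.
#' @param path file path.
#' @return `read_ecg()` returns an [ecg_record()]; `write_ecg()` returns
#'   `path` invisibly.
#' @examples
#' rec <- ecg_record(sin(1:100 / 5), fs = 100)
#' f <- tempfile(fileext = ".csv")
#' write_ecg(rec, f)
#' rec2 <- read_ecg(f)
#' all.equal(rec$MLII, rec2$MLII)
#' @export
write_ecg <- function(record, path) {
  fs <- ecg_fs(record)
  leads <- ecg_leads(record)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", fs), con)
  writeLines(paste(leads, collapse = ","), con)
  mat <- as.matrix(record[, leads, drop = FALSE])
  writeLines(apply(format(mat, digits = 10, trim = TRUE, scientific = FALSE),
    1, paste,
    collapse = ","
  ), con)
  invisible(path)
}

#' @rdname write_ecg
#' @export
read_ecg <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 2 || !grepl("^#\\s*fs\\s*=", lines[1])) {
    abort(sprintf("Malformed header in %s: line 1 must be '# fs=<Hz>' (got: %s)",
      path, if (length(lines)) lines[1] else "<empty file>"))
  }
  fs <- suppressWarnings(as.numeric(sub("^#\\s*fs\\s*=\\s*", "", lines[1])))
  if (is.na(fs) || fs <= 0) {
    abort(sprintf("Malformed header in %s: cannot parse sampling rate from line 1.", path))
  }
  leads <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  leads <- trimws(leads)
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body) == 0) abort(sprintf("No data rows in %s.", path))
  parts <- strsplit(body, ",", fixed = TRUE)
  widths <- lengths(parts)
  if (any(widths != length(leads))) {
    bad <- which(widths != length(leads))[1]
    abort(sprintf(
      "Inconsistent lead lengths in %s: data row %d has %d values, expected %d.",
      path, bad, widths[bad], length(leads)
    ))
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(parts))),
    ncol = length(leads), byrow = TRUE
  )
  if (anyNA(mat)) {
    bad <- which(rowSums(is.na(mat)) > 0)[1]
    abort(sprintf("Non-numeric or NaN cell in %s at data row %d.", path, bad))
  }
  ecg_record(mat, fs = fs, leads = leads, origin = path)
}

#' Write and read annotation tracks
#'
#' An annotation track is a tibble of `(sample, label, lead)` events with
#' 0-based, non-decreasing sample indices and labels from the fixed
#' vocabulary `P, Pon, Poff, QRSon, R, QRSoff, T, Toff, beat`.
#'
#' @param track tibble with columns `sample`, `label` and optionally `lead`.
#' @param path file path (TSV).
#' @param record optional [ecg_record()]; when given, indices are validated
#'   against the record length.
#' @return `read_annotations()` returns the track tibble; `write_annotations()`
#'   returns `path` invisibly.
#' @export
write_annotations <- function(track, path, record = NULL) {
  track <- validate_annotations(track, record)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("sample\tlabel\tlead", con)
  if (nrow(track) > 0) {
    writeLines(sprintf("%d\t%s\t%s", track$sample, track$label, track$lead), con)
  }
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path, record = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0 || !identical(strsplit(lines[1], "\t")[[1]][1:2], c("sample", "label"))) {
    abort(sprintf("Malformed annotation header in %s.", path))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(validate_annotations(tibble(
      sample = integer(), label = character(), lead = character()
    )))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  track <- tibble(
    sample = suppressWarnings(as.integer(vapply(parts, `[`, "", 1))),
    label = vapply(parts, `[`, "", 2),
    lead = vapply(parts, function(p) if (length(p) >= 3) p[3] else "*", "")
  )
  if (anyNA(track$sample)) {
    abort(sprintf(
      "Non-integer sample index in %s at data row %d.",
      path, which(is.na(track$sample))[1]
    ))
  }
  validate_annotations(track, record)
}

#' @rdname write_annotations
#' @export
validate_annotations <- function(track, record = NULL) {
  if (!all(c("sample", "label") %in% names(track))) {
    abort("Annotation track needs `sample` and `label` columns.")
  }
  if (!"lead" %in% names(track)) track$lead <- "*"
  track <- as_tibble(track[, c("sample", "label", "lead")])
  track$sample <- as.integer(track$sample)
  bad <- setdiff(unique(track$label), ANNOTATION_LABELS)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown annotation label(s): %s. Allowed: %s.",
      paste(bad, collapse = ", "), paste(ANNOTATION_LABELS, collapse = ", ")
    ))
  }
  if (nrow(track) > 0 && any(track$sample < 0)) {
    abort("Annotation sample indices must be >= 0.")
  }
  if (is.unsorted(track$sample)) {
    track <- track[order(track$sample), ]
  }
  if (!is.null(record) && nrow(track) > 0 && max(track$sample) >= nrow(record)) {
    abort(sprintf(
      "Annotation index %d out of range for a %d-sample record.",
      max(track$sample), nrow(record)
    ))
  }
  track
}

#' Convert delineation output to an annotation track
#'
#' Flattens a fiducial table (one row per beat) into the long
#' `(sample, label, lead)` annotation format.
#'
#' @param fiducials tibble returned by [delineate()].
#' @param lead lead name recorded in the track.
#' @return annotation track tibble.
#' @export
fiducials_to_annotations <- function(fiducials, lead = "*") {
  cols <- c(
    p_on = "Pon", p_peak = "P", p_off = "Poff",
    qrs_on = "QRSon", r_peak = "R", qrs_off = "QRSoff",
    t_peak = "T", t_off = "Toff"
  )
  rows <- lapply(names(cols), function(cn) {
    v <- fiducials[[cn]]
    keep <- !is.na(v)
    tibble(sample = as.integer(v[keep]), label = cols[[cn]], lead = lead)
  })
  validate_annotations(bind_rows(rows))
}
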