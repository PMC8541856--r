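#' Pipeline configuration
#'
#' All tunable constants of the detection pipeline in one nested list.  The
#' defaults reproduce the method's published constants exactly: the positive
#' threshold is 2/5 of the mean of the ten largest positive modulus maxima,
#' the negative threshold 1/3 of the mean of the ten most negative, and an
#' extremum pair must be closer than 100 ms to be accepted.
#'
#' @param ... named overrides, e.g. `ecg_config(eval = list(tol_ms = 50))`.
#'   Overrides are merged recursively into the defaults.
#' @return list of class `ecg_config`.
#' @examples
#' cfg <- ecg_config()
#' cfg$pwave$px_factor
#' @export
ecg_config <- function(...) {
  defaults <- list(
    wavelet = list(
      max_scale = 5L, # dyadic scales 2^1 .. 2^5
      qrs_scales = c(1L, 2L, 3L), # cross-scale QRS evidence
      p_scale = 4L # P and T localization scale
    ),
    qrs = list(
      rms_factor = 0.3, # threshold = factor x running RMS
      rms_window_s = 2,
      pair_max_ms = 120, # max extremum-pair gap for a QRS
      cross_scale_ms = 40,
      sharpness_min = 0.2, # scale-1 / scale-2 amplitude ratio gate
      amp_gate = 0.25, # x median of the strongest pair strengths
      refractory_ms = 200,
      searchback_factor = 1.66, # RR gap triggering search-back
      boundary_frac = 0.1, # onset/offset coefficient decay fraction
      boundary_max_ms = 100,
      snap_ms = 30 # R snapped to signal extremum within this window
    ),
    segment = list(
      pre_max_s = 0.45, # P search segment: S_Q - min(this, rr_frac*RR)
      rr_frac = 0.9,
      pre_end_s = 0.03 # ... up to S_Q - this
    ),
    pwave = list(
      px_factor = 2 / 5, # Eq-style positive threshold constant
      py_factor = 1 / 3, # negative threshold constant
      top_k = 10L, # extrema entering the threshold means
      pair_max_ms = 100, # pair acceptance gap
      slope_min = 0, # |K| floor; 0 disables the slope gate
      boundary_frac = 0.05, # P onset/offset decay fraction
      boundary_max_ms = 150,
      refine = TRUE, # signal-domain onset/offset refinement
      refine_frac = 0.01, # boundary at this fraction of wave amplitude
      qrs_refine_frac = 0.002, # relative to R; the onset wave (Q) is small
      secondary_gate = 0.5, # x median primary pair strength
      secondary_min_primary = 3L,
      corr_min = 0.5, # P-template verification gate (anchored candidates)
      corr_min_secondary = 0.8, # unanchored candidates must match closely
      corr_half_ms = 60, # template half-width
      corr_min_primary = 5L, # primaries needed to build the template
      p_refractory_ms = 250,
      merge_ms = 200 # primary/secondary duplicate window
    ),
    twave = list(
      after_qrs_s = 0.08, # T window: [QRS offset + this, ...]
      max_s = 0.4,
      rr_frac = 0.6,
      pair_max_ms = 250 # T is wide; its extremum pair spans > 100 ms
    ),
    rules = list(
      pac_prematurity = 0.2, # P earlier than (1-this) x median PP
      pac_pr_min_ms = 120,
      conduction_ms = 300, # nonconducted P: no QRS within this
      circ_var_min = 0.5, # AV dissociation circular-variance gate
      assoc_max_ms = 400, # P-to-QRS association cap
      brady_bpm = 60,
      pwd_ms = 40,
      min_beats = 5L
    ),
    eval = list(
      tol_ms = 75, # match tolerance
      er_denominator = "tp_fn" # or "tp_fp_fn"
    )
  )
  out <- merge_config(defaults, list(...))
  structure(out, class = c("ecg_config", "list"))
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read and write pipeline configuration files
#'
#' Configurations serialize to YAML and round-trip losslessly.
#'
#' @param config an [ecg_config()].
#' @param path file path.
#' @return `read_config()` returns an `ecg_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  do.call(ecg_config, vals)
}
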