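# Synthetic detection benchmark: scripted arrhythmia classes scored
# end-to-end (generate -> delineate -> match -> Er/Se/Pp).

#' Benchmark scripts for one arrhythmia class
#'
#' The `"ventricular"` class pools premature-atrial-contraction and
#' complete-AV-dissociation records (the dissociation lattice uses the
#' 0.6818 s / 2.0 s intervals, i.e. 88 bpm atrial over 30 bpm ventricular);
#' the `"atrial"` class pools sinus and sinus-bradycardia records.  Each
#' seed contributes roughly 200 annotated beats per class.
#'
#' @param class `"ventricular"` or `"atrial"`.
#' @param seed integer seed for the records' noise.
#' @param fs sampling rate, Hz.
#' @param snr_db Gaussian SNR of each record, dB.
#' @param baseline_amp baseline-wander amplitude, mV.
#' @return list of [rhythm_script()]s.
#' @export
benchmark_scripts <- function(class = c("ventricular", "atrial"), seed = 1L,
                              fs = 250, snr_db = 20, baseline_amp = 0.1) {
  class <- match.arg(class)
  nz <- noise_spec(snr_db = snr_db, baseline_amp = baseline_amp)
  if (class == "ventricular") {
    list(
      rhythm_script("pac",
        atrial_interval = 0.9, duration = 100, fs = fs,
        noise = nz, seed = seed
      ),
      rhythm_script("av_dissociation",
        atrial_interval = 0.6818,
        ventricular_interval = 2.0, duration = 60, fs = fs,
        noise = nz, seed = seed + 1000L
      )
    )
  } else {
    list(
      rhythm_script("sinus",
        atrial_interval = 0.8, duration = 80.8, fs = fs,
        noise = nz, seed = seed
      ),
      rhythm_script("bradycardia",
        atrial_interval = 1.2, duration = 120, fs = fs,
        noise = nz, seed = seed + 1000L
      )
    )
  }
}

#' Run the P-wave detection benchmark for one class
#'
#' Generates the class records for every seed, runs [delineate()], matches
#' detected P peaks to the generator truth at the millisecond tolerance and
#' pools the counts into one [detection_score()].
#'
#' @param class `"ventricular"` or `"atrial"`.
#' @param seeds integer vector of seeds (one record set each).
#' @param tol_ms matching tolerance, ms.
#' @param config an [ecg_config()].
#' @inheritParams benchmark_scripts
#' @return a `detection_score`; the number of annotated beats scored is in
#'   attribute `n_beats`.
#' @export
pwave_benchmark <- function(class = c("ventricular", "atrial"), seeds = 1:10,
                            tol_ms = 75, fs = 250, snr_db = 20,
                            baseline_amp = 0.1, config = ecg_config()) {
  class <- match.arg(class)
  tp <- fp <- fn <- n_beats <- 0L
  for (s in seeds) {
    for (script in benchmark_scripts(class, s, fs, snr_db, baseline_amp)) {
      sim <- suppressWarnings(generate_ecg(script))
      fid <- delineate(sim$record, config = config)
      det <- fid$p_peak[!is.na(fid$p_peak)]
      tru <- sim$truth$peak[sim$truth$wave == "P"]
      m <- match_events(det, tru, tol = tol_ms / 1000 * fs)
      tp <- tp + m$tp
      fp <- fp + m$fp
      fn <- fn + m$fn
      n_beats <- n_beats + length(tru)
    }
  }
  out <- detection_score(tp, fp, fn, tolerance_ms = tol_ms, config = config)
  attr(out, "n_beats") <- n_beats
  out
}

#' Recover the scripted rates of the narrated rhythms
#'
#' Builds the two noiseless rhythm constructions (complete AV dissociation
#' with P-P 0.6818 s and R-R 2.0 s; regular P at 0.9677 s with the QRS
#' dropped after every 5th P), runs the full pipeline and returns the rates
#' implied by the detected fiducials (Eq-style `60 / mean(interval)`),
#' rounded to integer bpm.
#'
#' @param fs sampling rate, Hz.
#' @param duration record length, s.
#' @param config an [ecg_config()].
#' @return tibble with `atrial_bpm_dissociation`,
#'   `ventricular_bpm_dissociation`, `p_bpm_dropped_qrs`.
#' @export
rate_recovery <- function(fs = 250, duration = 60, config = ecg_config()) {
  dis <- suppressWarnings(generate_ecg(rhythm_script("av_dissociation",
    atrial_interval = 0.6818, ventricular_interval = 2.0,
    duration = duration, fs = fs
  )))
  fd <- delineate(dis$record, config = config)
  lf_d <- lead_features(fd)
  drp <- generate_ecg(rhythm_script("dropped_qrs",
    atrial_interval = 0.9677, duration = duration, fs = fs
  ))
  fr <- delineate(drp$record, config = config)
  lf_r <- lead_features(fr)
  tibble(
    atrial_bpm_dissociation = lf_d$atrial_bpm,
    ventricular_bpm_dissociation = lf_d$ventricular_bpm,
    p_bpm_dropped_qrs = lf_r$atrial_bpm
  )
}
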