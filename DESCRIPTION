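Package: pwaver
Title: Wavelet P-Wave Delineation and Rhythm Analysis for Dynamic ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and delineates P waves in dynamic (ambulatory) ECG
    recordings with an undecimated quadratic-spline wavelet transform:
    signed modulus-extremum pairs are screened by adaptive amplitude
    thresholds and a 100 ms pairing window, and wave peaks are localized
    at the zero crossing between accepted pairs.  Includes a QRS
    detector to anchor the P-wave search segment, fiducial feature
    computation (PR interval, P-wave duration and amplitude, P-wave
    dispersion, atrial and ventricular rates) with normal-range flags,
    rule-based rhythm assessment (AV dissociation, intermittent block,
    premature atrial contractions, sinus bradycardia), a detector
    evaluation harness (sensitivity, positive predictivity, failed
    detection rate), and an annotated synthetic-ECG generator so that
    every stage is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
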