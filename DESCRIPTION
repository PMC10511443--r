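Package: dualppg
Title: Continuous Blood Pressure Estimation from Dual-Wrist Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cuffless continuous blood pressure estimation from
    dual photoplethysmography (PPG) sensors worn on the palmar and dorsal
    sides of the wrist, together with contact-pressure and skin-temperature
    interface sensors. Implements a synthetic multichannel session generator
    with known latent hemodynamics, signal conditioning (zero-phase low-pass
    filtering, wavelet denoising, baseline/pulsatile decomposition, z-score
    standardization, windowing), beat segmentation and fiducial delineation,
    pulse-waveform feature extraction including the dual-channel DC baseline
    difference, a multilayer-perceptron fusion model mapping window features
    to systolic and diastolic pressure, and evaluation under
    leave-one-subject-out cross-validation with Bland-Altman limits of
    agreement, AAMI pass/fail and BHS grading.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    signal,
    data.table,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
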