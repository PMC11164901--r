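Package: ramanclass
Title: Intraoperative Raman Spectroscopy Tissue Classification Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for probe-based Raman spectroscopy
    tissue diagnostics: conditioning of raw CCD acquisitions (dark-count
    subtraction, cosmic-ray removal, wavenumber calibration, instrument
    response correction, BubbleFill baseline removal, Savitzky-Golay
    smoothing, standard-normal-variate normalization), a spectral quality
    factor with ROC-guided cutoff selection, Gaussian peak-feature
    engineering with consensus-peak retention and random-forest feature
    ranking, and patient-grouped linear support-vector-machine
    classification with grid-searched hyperparameters and holdout ROC
    evaluation. Includes a synthetic cohort generator that emulates
    two-site neurosurgical Raman studies (fluorescence baselines, shot
    noise, cosmic rays, patient and site random effects, class-dependent
    Raman bands) with ground truth for validation, and the power and
    effect-size statistics used to size such studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    ranger,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
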