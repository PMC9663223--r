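Package: fnirsupb
Title: Detecting Unplanned Purchase Behavior from Prefrontal fNIRS Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete, seeded analysis pipeline for detecting unplanned
    purchase behavior (UPB) from prefrontal functional near-infrared
    spectroscopy (fNIRS) recordings acquired under a Buy-One-Get-One-Free
    (BOGOF) shopping paradigm. Provides a block-design dual-wavelength
    simulator with double-gamma hemodynamics and physiological noise,
    modified Beer-Lambert conversion of optical density to hemoglobin
    concentration changes, zero-phase band-pass filtering, task-locked
    epoching with baseline correction, six time-domain features (mean,
    variance, kurtosis, skewness, slope, area) with min-max rescaling,
    per-subject linear support-vector-machine classification under repeated
    stratified cross-validation, ROC/AUC reliability reporting, an
    80-percent-accuracy detection verdict, and the accompanying behavioral
    and self-report t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
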