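Package: pupage
Title: Intra-Puparial Age Estimation for Chrysomya nigripes from
    Morphology and ATR-FTIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-track estimation of the intra-puparial age of the blow fly
    Chrysomya nigripes for minimum postmortem interval (PMI_min) casework.
    One track converts field observations of organ-level developmental
    sub-stages (compound eyes, antennae, mouthparts, thorax, legs, wings,
    abdomen) into an age window in hours since pupariation, using packaged
    minimum/maximum duration tables at six constant temperatures with linear
    temperature interpolation and interval intersection. The other track is a
    chemometric pipeline for ATR-FTIR puparium spectra: fingerprint-region
    cropping, Savitzky-Golay smoothing, standard normal variate scaling,
    baseline correction and mean centering, followed by PCA reduction and
    PLS-DA or random-forest classification of age classes with
    macro-averaged accuracy, precision, recall and F1 over repeated
    stratified splits. A parametric generator of synthetic puparium spectra
    with age-dependent band amplitudes supports testing and power analysis,
    and the two evidence tracks are fused by interval intersection into a
    single PMI_min window.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
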