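Package: msemeg
Title: Multiscale Entropy Analysis of Multichannel Resting-State Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Coarse-grained sample entropy (multiscale entropy) analysis for
    multichannel electrophysiological recordings (MEG/EEG): scale-region kappa
    statistics, phase-randomized surrogate decomposition of entropy into
    amplitude and phase components, channel-wise group comparison with false
    discovery rate control, MSE and band-power feature extraction, and
    lasso-regularized linear discriminant classification with repeated
    balanced validation splits. Includes a synthetic two-group cohort
    generator with controllable spectral slope, band oscillations and
    phase-coupled (nonlinear) structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    signal,
    glmnet,
    MASS,
    tibble,
    dplyr,
    tidyr,
    jsonlite,
    rlang,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
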