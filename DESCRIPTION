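Package: spectralforest
Title: Random-Forest Prediction of Cognition from Resting-State EEG Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A transdiagnostic analysis pipeline that predicts cognitive test
    performance from resting-state EEG power spectra. Multichannel recordings
    are reduced to subject-by-(channel x 1-Hz-bin) log-power features with
    Welch-averaged Hann-windowed periodograms, residualized on age and gender,
    and fed to bagged regression trees with out-of-bag prediction. Model fit is
    the Nash-Sutcliffe efficiency, significance comes from an outcome-
    permutation null distribution, and predictive EEG features are profiled via
    out-of-bag permutation importance (frequency profiles, peak selection,
    scalp topographies, and signed univariate effects at the top channels).
    Clinical follow-up statistics (Welch's heteroscedastic ANOVA across
    diagnostic groups, symptom-dimension correlations, and one-vs-rest
    diagnosis-prediction control forests) and a synthetic-cohort generator with
    known ground-truth couplings are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ranger,
    withr
Config/testthat/edition: 3
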