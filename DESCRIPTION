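Package: saccdecode
Title: Time-Resolved EEG Decoding of Spatial Frequency Across Saccades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for time-resolved multivariate
    decoding of visual spatial frequency from EEG during stable fixation and
    saccade preparation. Provides a synthetic session generator (trial
    schedules, gaze traces, continuous 64-channel EEG with embedded
    ground-truth discriminative latencies), velocity-based saccade detection
    with trial-exclusion rules, EEG preprocessing (resampling, mastoid
    re-referencing, zero-phase filtering, ocular component selection,
    epoching and baseline correction), time-resolved shrinkage-LDA
    classification with cross-location and cross-condition generalization,
    and JZS Bayes-factor onset-latency inference with leave-two-out
    jackknife confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
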