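Package: qeegpredict
Title: Quantitative EEG Features and Random-Forest Outcome Prediction
    for Moderate-to-Severe Traumatic Brain Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Artifact-screened quantitative EEG (qEEG) feature extraction
    from continuous 19-channel intensive-care EEG, fused with clinical
    admission covariates (the IMPACT parameter set, age and mean arterial
    pressure) in a Random-Forest classifier for 12-month neurological
    outcome prediction after moderate-to-severe traumatic brain injury.
    Includes EDF input with 10-20 montage validation, common-average and
    longitudinal-bipolar derivations, per-epoch amplitude/variance artifact
    rejection, 23 spectral and time-domain features (band powers, alpha/delta
    ratio, spectral edge frequency, band-power variability, pairwise brain
    symmetry index, centre of gravity, mean amplitude, coherence, Shannon
    entropy, regularity), leave-one-patient-out evaluation with ROC/AUC and
    50% confidence intervals, and an outcome-conditioned synthetic cohort
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    randomForest,
    pROC,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
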