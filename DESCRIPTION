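Package: predinf
Title: Normative and Flexible Learning Models for Predictive-Inference
    (Helicopter) Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying adaptive learning in change-point
    ("helicopter") predictive-inference tasks. Provides a synthetic task and
    agent generator; a reduced-Bayesian normative learning model tracking
    change-point probability and relative uncertainty, with catch-trial cue
    combination; a flexible model family with principled deviations from
    normativity (surprise insensitivity, hazard-rate mis-estimation,
    uncertainty underestimation, subjective noise perception); maximum
    a-posteriori fitting of the flexible model to trial-by-trial updating
    behaviour with a heteroscedastic response likelihood; sliding-window
    heteroscedasticity-weighted ridge regression of updates on prediction
    errors and model-derived regressors; and cluster-mass permutation tests,
    leave-one-subject-out coefficient extraction and nested F-tests for
    group-level inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
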