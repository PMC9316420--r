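Package: dtsurv
Title: Discrete-Time Survival Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds survival prediction models in a discrete-time framework.
    Continuous right-censored follow-up is discretized onto an interval grid
    (cut points at event-time quantiles within a prediction horizon),
    expanded into a person-period data set, and the per-interval hazard is
    fit as a binary classification problem, either with link-based models
    (the continuation-ratio/logistic model and complementary log-log,
    probit, log-log and log variants) or with any pluggable binary
    classifier. Predicted hazards compose into individual survival curves.
    Predictive performance is assessed with censoring-adjusted
    (inverse-probability-of-censoring-weighted) time-dependent AUC and
    Brier score, null-model scaled R-squared and the integrated Brier
    score. Includes subject-level data splitting, hyperparameter tuning
    that treats the number of intervals as a tuning parameter, a
    benchmarking pipeline, and a parametric simulator with oracle access
    to the true survival function.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    ranger,
    rpart
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
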