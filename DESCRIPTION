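Package: behavpred
Title: Behavioural Types and Predictability from Animal Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies among-individual variation in behaviour from GPS
    telemetry. Converts raw fix data into daily movement metrics (distance
    to landscape features, total path length, average hourly speed), fits
    Bayesian double-hierarchical Gaussian models with correlated individual
    random effects in the mean and residual-dispersion submodels, and
    derives repeatability, the coefficient of variation in predictability
    (CVp), and behavioural type-predictability syndromes. Selection on
    behavioural types and predictability is estimated by refitting logistic
    survival models across the posterior draws of individual effects, so
    that uncertainty in behavioural measures propagates into the selection
    estimates. A synthetic-data generator (landscape, GPS tracks, daily
    traits, survival outcomes) with known ground truth supports validation
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
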