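Package: growthssd
Title: Bayesian Sample Size Determination for Longitudinal Growth Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sample size determination for two-arm longitudinal intervention
    trials analysed with two-level linear or log-linear growth models and
    evaluated with the approximate adjusted fractional Bayes factor (AAFBF).
    Trials are simulated under competing hypotheses about the
    treatment-by-time interaction, each simulated dataset is fitted with a
    fast profiled-likelihood estimator for balanced designs, Bayesian power
    is estimated by Monte Carlo, and the minimal number of subjects meeting
    a target power is located by binary search, with an optional sensitivity
    analysis over the fraction of information used to build the default
    prior.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
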