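Package: apcforecast
Title: Lee-Carter and Bayesian Age-Period-Cohort Forecasting of
    Cause-Specific Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting cause-specific death rates and death counts
    on age-group by calendar-year grids. Fits the Lee-Carter model (singular
    value decomposition of centred log-rates with a random-walk-with-drift
    mortality index) and a hierarchical Bayesian age-period-cohort model on
    the logit of the death probability with first- or second-order random-walk
    smoothing priors, an optional cell-level heterogeneity term, and a
    Metropolis-within-Gibbs sampler. Supports model comparison by the deviance
    information criterion and by hold-out mean absolute percent error, and
    projection of future death counts under a constant-rate counterfactual
    versus continued-decline forecasts applied to population projections.
    Includes a synthetic-data generator emulating an age-exponential mortality
    schedule, a decelerating period decline, small cohort effects,
    overdispersion, and an ageing population.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
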