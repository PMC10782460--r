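Package: recurshr
Title: Proportional-Rates Models and Standardised Ratios for Clustered
    Recurrent Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits semi-parametric proportional rates models to clustered
    recurrent-event data (e.g. hospital admissions across healthcare
    facilities) on an integer calendar-day grid. Covariate effects come from
    a facility-stratified Breslow partial likelihood, the baseline rate is a
    non-parametric function of calendar time, and high-dimensional facility
    effects are estimated by a fixed-point iteration under the constraint
    that observed and expected event totals agree, which makes indirect and
    direct standardised ratios coincide. Includes naive and robust
    (sandwich) variance estimators for both parameter sets, a Monte-Carlo
    simulation harness with staggered entry and optional gamma frailty,
    Schoenfeld-type residual diagnostics, observed/expected series, and a
    builder for time-varying COVID-19 stage covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    jsonlite
Config/testthat/edition: 3
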