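Package: traitnet
Title: Trait Covariation Networks for Behavioral Cohort Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores cognitive, behavioral, physiological and life-history traits
    from raw trial records of a wild fish cohort (T-maze learning with a
    days-to-criterion rule, reversal learning, spatial memory, motor and visual
    lateralization, open-field, scototaxis, sociability, ventilation-based
    metabolism, growth), provides a Monte-Carlo chance-performance null with an
    exact dynamic-programming oracle for criterion-based maze learning,
    univariate and repeated-measures statistics including repeatability with
    parametric bootstrap, multiple imputation by chained equations with
    predictive mean matching, and regularized partial-correlation network
    inference (graphical lasso with extended BIC model selection) with strength,
    eigenvector and expected-influence centralities, nonparametric edge
    bootstrap, and case-dropping stability (CS-coefficient) diagnostics. A
    synthetic-cohort generator with a configurable latent trait covariance makes
    the full pipeline testable without the original field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    car,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    broom,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
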