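Package: dsemr
Title: Two-Level Bayesian Vector Autoregression for Experience-Sampling Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Dynamic structural equation modelling (DSEM) for intensive
    longitudinal data from experience-sampling / ecological momentary
    assessment studies. Fits a two-level Bayesian lag-1 vector
    autoregression with latent person-mean centering, person-varying
    autoregressive and cross-lagged dynamics, an hour-of-measurement
    trend, missing-data augmentation inside the Gibbs sampler, and
    between-person correlations of the random dynamics with baseline
    covariates. Includes a synthetic experience-sampling study generator
    with known ground truth (signal-contingent prompt schedules,
    person-varying VAR(1) dynamics, compliance-driven missingness), a
    one-hour time-grid discretizer for unequally spaced prompts,
    within-person standardized effect tables with credible intervals,
    averaged within-person R-squared, and convergence diagnostics.
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
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    coda,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
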