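Package: peirs
Title: Risk-Sensitive Reinforcement Learning for Experienced and Described Risks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical model fitting for context-dependent
    risk-taking in bandit tasks with Gaussian reward distributions. Implements
    the Prediction Error Induced Risk-Seeking (PEIRS) model, in which the
    utility of an option combines its learned mean value, its learned outcome
    spread, and a context signal that compares the offered options against the
    overall reward environment, alongside the nested Rescorla-Wagner baseline.
    Provides generators for experience-based and description-based risk task
    schedules, synthetic agent cohorts (including hunger-like parameter
    regimes), empirical-Bayes expectation-maximization fitting with Laplace
    posterior approximations, BIC model comparison, parameter-recovery
    diagnostics, and the behavioral risk-preference statistics (context-wise
    risky-choice proportions, mixed-trial accuracy, fully-within 2x2 repeated
    measures contrasts, signed-rank tests).
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
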