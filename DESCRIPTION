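Package: lagmed
Title: Lagged Multilevel Mediation Analysis of Session-by-Session
    Therapy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying change processes in psychological therapy
    from routine session-by-session outcome monitoring. Scores weekly
    questionnaires (SPWSS, SCQ composite and related scales), builds
    lagged within/between (group-mean-centered) modelling datasets, and
    fits a two-level, two-equation mediation model by maximum likelihood
    in which the time-to-process path (a) and the direct time-to-outcome
    path (c') are random across participants while the lagged
    process-to-outcome path (b) is fixed. Computes indirect effects
    (a x b), percent mediation, Wald tests, reversed-direction models,
    intraclass correlations, and pre/post effect sizes, and provides a
    calibrated synthetic longitudinal cohort generator for estimator
    validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
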