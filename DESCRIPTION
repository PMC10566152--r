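Package: berksonjem
Title: Berkson Error Adjustment for Job-Exposure-Matrix Based Risk Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood estimation of exposure-response slopes (log odds
    ratios) from job-exposure-matrix (JEM) based occupational exposure histories,
    with adjustment for Berkson measurement error under a gamma exposure model.
    Provides series-expanded Berkson-adjusted likelihoods for ordinary logistic,
    Poisson, and conditional logistic regression, surrogate comparators based on
    the arithmetic mean, geometric mean, and modified geometric mean, adaptive
    quadrature oracles for the defining marginal-likelihood integrals, a
    synthetic cohort generator emulating an occupational case-control study, and
    a two-level Monte Carlo study engine reporting bias, standard error, and
    root-mean-square error for each estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    parallel,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
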