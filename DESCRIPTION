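Package: ecoincidence
Title: County-Level Ecological Analysis of Cancer Incidence and
    Population Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for county-level ecological regression of cancer
    incidence against population-level exposures: direct age
    standardization of incidence rates with inclusion filtering,
    segmented log-linear trend analysis (joinpoint placement, annual
    percent change and average annual percent change with confidence
    intervals), two-stage risk-factor screening with bivariable and
    covariate-adjusted linear models, correlation-constrained exhaustive
    best-subset model selection by the Bayesian information criterion
    with forced adjustment covariates, and pooling, nested-model pruning
    and comparability ranking of candidate models. Includes a synthetic
    county-data generator with planted effects for parameter-recovery
    benchmarking, and an end-to-end pipeline with sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
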