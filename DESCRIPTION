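Package: clonefit
Title: Clone Fitness Inference from Longitudinal Deep-Sequencing Variant Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing clonal hematopoiesis from longitudinal
    targeted deep-sequencing data. Implements a likelihood-based filter for
    time series of variant allele frequencies (LiFT) that separates expanding
    somatic clones from sequencing artifacts by Bayesian model comparison,
    joint grid-based Bayesian inference of clone fitness and stem-cell pool
    size under a linear birth-death model, selection of clonal structures
    (which mutations co-occur on one clone), gene-level fitness summaries and
    nonparametric comparisons, and clinical referral-time forecasting. A
    seeded synthetic-cohort simulator, including an exact Gillespie
    birth-death simulator, makes the whole pipeline testable without access
    to cohort data.
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
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
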