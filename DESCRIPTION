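Package: spenwas
Title: Spatial Environment-Wide Association Studies for Areal Disease Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage ecological analysis pipeline for area-level disease
    counts: a frequentist environment-wide association study (EnWAS) screen of
    many exposures by univariable Poisson regression with indirectly
    standardised expected-count offsets and Bonferroni control; Bayesian
    disease mapping with a BYM2 convolution model (scaled intrinsic
    conditional autoregressive plus unstructured heterogeneity, combined
    through a mixing parameter) fitted by Markov chain Monte Carlo, with
    posterior relative-risk surfaces and exceedance-probability
    classification; and a correlation-guided multivariable spatial ecological
    regression. Includes indirect age-sex standardisation, population-weighted
    exposure aggregation, GAL adjacency input/output, and a synthetic-region
    generator producing areal populations, intercorrelated spatially smooth
    exposures and Poisson counts with known ground truth, so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
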