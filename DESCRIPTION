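Package: thermoRRM
Title: Reaction-Norm Random-Regression Analysis of Dairy Heat Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genetic analysis of dairy test-day records under heat stress.
    Builds temperature-humidity-index (THI) heat-load covariates from hourly
    weather, fits multi-trait repeatability reaction-norm animal models with
    general and thermotolerance intercept/slope random effects, estimates
    variance components by Gibbs sampling, performs single-step genomic BLUP
    whole-genome scans via SNP-effect backsolving and 2.0 Mb window variance
    decomposition, and tests gene-set enrichment of candidate thermotolerance
    genes with the hypergeometric (Fisher exact) test. Includes a synthetic
    data generator (pedigree, gene-dropped genotypes, seasonal THI series,
    model-generated phenotypes) so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
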