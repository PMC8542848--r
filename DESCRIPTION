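Package: mcbayes
Title: Multi-Class Bayesian Alphabet Models for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-trait and multiple-trait whole-genome Bayesian regression
    in which markers are allocated (possibly overlappingly) into SNP classes
    and each class receives its own Bayesian Alphabet prior (RR-BLUP, BayesA,
    BayesB, BayesCPi, or Bayesian LASSO). Includes a Gibbs sampling engine
    with multi-trait variable selection via trait-inclusion indicators, prior
    elicitation from phenotypic (co)variance, a simulator for annotation-
    enriched quantitative trait loci, cross-validation and ensemble
    evaluation, and Gelman-Rubin convergence diagnostics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
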