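Package: poolgea
Title: Genome-Environment Association Scans for Pool-Seq Allele Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian hierarchical genome-environment association (GEA)
    analysis for pooled-sequencing allele read counts. Estimates the scaled
    covariance matrix of population allele frequencies (Omega) by
    Metropolis-within-Gibbs sampling, computes the XtX differentiation
    statistic, and scans SNPs for association with standardized environmental
    covariates under a spike-and-slab (auxiliary-variable) regression,
    reporting posterior inclusion probabilities and Bayes factors in deciban.
    Includes the surrounding pipeline: a five-step post-calling SNP filter
    cascade, fold-enrichment tests for annotation categories and selection
    signatures with circular-permutation nulls, candidate-region calling from
    top SNPs with gene overlap, climate-covariate pruning and PCA, PCNM
    spatial-grain decomposition, and a power-study simulator with ROC and
    precision-recall evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    vegan,
    yaml,
    digest,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
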