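Package: chd8net
Title: Chromatin-Target Enrichment, Knockdown Expression Analysis and
    Network Risk Modelling for CHD8
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packages", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit connecting CHD8 ChIP-seq binding to autism
    risk genetics. Provides reproducible-peak annotation against gene models,
    covariate-weighted (mutability and promoter-size) permutation tests for
    risk-gene enrichment among bound promoters, seed-anchored spatiotemporal
    co-expression networks with seed-permutation enrichment tests, a
    Poisson/negative-binomial knockdown differential-expression pipeline with
    variance-to-mean-ratio filtering, rank-based gene-set and pathway tests
    with spline-residual scoring, and an extended DAWN hidden Markov random
    field in which a binding covariate d captures the elevated risk of
    chromatin-factor targets, with a smoothed-bootstrap test for d > 0.
    A synthetic-data module generates every pipeline input with planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    MASS,
    splines,
    glmnet,
    jsonlite,
    Rcpp,
    IRanges,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
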