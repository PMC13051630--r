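Package: crossgp
Title: Genomic Prediction of F1 Hybrid Performance from Parental Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting phenotypes of F1 crosses from parental
    genotypes and phenotypes in highly homozygous crop panels. Summarizes
    multi-year phenotypes as best linear unbiased predictors (BLUPs) with
    broad-sense heritability, quantifies mid-parent and high-parent
    heterosis in F1 progeny, estimates F1 genotypes from parental marker
    data, trains eleven genomic prediction models (penalized regressions,
    kernel GBLUP with additive, dominance and Gaussian relationship
    matrices, Bayesian whole-genome regressions, random forest) on inbred
    lines only, and analyzes how heterosis inflates per-individual
    prediction error. A synthetic-data module generates inbred panels,
    crosses and multi-year phenotypes with tunable dominance so the whole
    workflow is testable without field data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    lme4,
    glmnet,
    ranger,
    vcfR,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
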