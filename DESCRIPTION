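Package: aquaGS
Title: Genomic Selection and GWAS for Aquaculture Breeding Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genomic prediction and genome-wide association analysis
    of quantitative traits in aquaculture breeding populations genotyped with
    reduced-representation SNP panels. Implements genotype quality control
    (call-rate and minor-allele-frequency filters, mean-dosage imputation,
    windowed r-squared tag-SNP pruning), the VanRaden genomic relationship
    matrix, GBLUP by restricted maximum likelihood, five Bayesian
    whole-genome regression models (BayesA, BayesB, BayesC, Bayesian LASSO,
    Bayesian ridge regression) fitted by Gibbs sampling, mixed-model
    association scans with Wald tests and candidate-gene windows, repeated
    k-fold cross-validated predictability, and marker-density reduction
    experiments with GWAS-ranked, random, and evenly spaced SNP sampling.
    A synthetic-population generator with correlated polygenic traits makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    vcfR,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
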