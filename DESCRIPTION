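Package: ddagwas
Title: Discrete Discriminant Analysis for Case-Control Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Collective inference of single-SNP and epistatic interaction
    effects in case-control genome-wide association data by discrete
    discriminant analysis. Genotype distributions of case and control groups
    are modeled separately as exponential families (inverse Ising/Potts
    models) fitted by exact enumeration, pseudo-likelihood, or mean-field
    covariance inversion under an l2 penalty; their parameter differences
    yield disease-risk effects. Includes penalized likelihood-ratio tests
    with permutation-resampled empirical nulls, cross-validated AUC risk
    prediction, an exhaustive-enumeration genotype simulator, a penalized
    logistic-regression baseline with marginal pairwise epistasis tests,
    PLINK text and binary file support, pathway-based SNP-set scoring, and
    binomial chromatin-state enrichment tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    fgsea
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
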