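Package: clonetrack
Title: Clonal Variety Identification and Ancestry Estimation from SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying clonally propagated crop varieties in
    farmers' fields from genome-wide biallelic SNP dosage data. Implements
    identity-by-state clone fingerprinting with a duplicate-calibrated
    identity threshold, Ward hierarchical clustering, reference-library
    collapsing and accession matching, maximum-likelihood admixture ancestry
    estimation by EM with masked-entry cross-validation over the number of
    founder populations, per-locus Weir-Cockerham FST and ancestry-informative
    marker panel selection, discriminant analysis of principal components
    (DAPC) for assumption-free validation of population structure, and a
    synthetic-data generator that emulates clonal field surveys with full
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    igraph,
    ape,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
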