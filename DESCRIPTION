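Package: methylsex
Title: Sex Classification and Differential Methylation from Whole-Genome
    Bisulfite Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse sex-specific DNA methylation in dioecious
    plants from per-cytosine bisulfite sequencing calls. Provides readers
    for Bismark coverage and cytosine-report files, per-cytosine
    differential methylation testing between sexes with
    Benjamini-Hochberg correction and effect-size thresholds,
    gene-feature (promoter/exon/intron) methylation profiles, 500 bp
    tile feature matrices, a penalized logistic regression classifier
    with supervised feature clustering, repeated cross-validation with
    feature-recurrence mapping, and a beta-binomial methylome simulator
    with a planted sex-linked differentially methylated gene.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
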