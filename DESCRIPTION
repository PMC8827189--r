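Package: gctherm
Title: Phylogenetic Comparative Analysis of Prokaryotic GC Content and
    Growth Temperature
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for phylogenetic comparative analysis of genomic
    base composition against growth temperature in bacteria and
    archaea.  Computes GC-content indexes (whole genome, protein
    coding, fourfold-degenerate sites, unannotated DNA, structural RNA
    genes) and reverse-complement-pooled dinucleotide frequencies from
    annotated genomes; estimates Pagel's lambda phylogenetic signal;
    fits phylogenetic generalized least squares (PGLS) regressions
    under Brownian-motion, Ornstein-Uhlenbeck (fixed root), Pagel's
    lambda and early-burst covariance models; runs phylogenetic paired
    t-tests, sister-pair rank contrasts with exact Wilcoxon
    signed-rank tests, and subsampling sensitivity analyses; detects
    discrete evolutionary jumps under a Levy (Brownian plus compound
    Poisson) trait model with per-branch jump posteriors,
    precision-recall threshold calibration and jump-change Spearman
    correlations; and measures nonlinearity of trait relationships
    with penalized-spline mixed models.  A synthetic-data module
    generates ultrametric trees, correlated traits with optional jumps
    and outlier clades, toy annotated genomes and gene presence
    matrices with known truth, so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    mgcv,
    nlme,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
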