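Package: retroforge
Title: Retrocopy Detection and Codon-Model Selection Analysis for Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects LINE-1 mediated retrocopies (processed pseudogenes) of a
    parent gene in a genome using intronless reciprocal-best-hit criteria with
    target-site-duplication and poly-A evidence, classifies syntenic
    pre-insertion sites across genomes, and analyses the molecular evolution of
    retrocopy families with codon substitution models: NG86 pairwise dN/dS,
    GY94 likelihoods by Felsenstein pruning, free-ratio and branch-site
    (Model A) fits with likelihood ratio tests, marginal ancestral
    reconstruction, empirical-Bayes site posteriors, and a Monte-Carlo neutral
    null for pairwise dN/dS. Substitutions at a protein-protein interface are
    partitioned by distance to the partner chain and classified by folding and
    binding free-energy changes. A truth-tracked synthetic-data generator
    (multi-exon genes, retrotransposed insertions with 5' truncation, poly-A
    tails, target-site duplications, mutational decay, and codon alignments
    evolved under per-branch per-site dN/dS) makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    BiocGenerics,
    ape,
    jsonlite,
    rtracklayer,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
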