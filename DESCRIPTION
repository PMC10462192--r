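Package: missplice
Title: Differential Mis-Splicing, Microexon and RNA-Binding Motif
    Enrichment Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying alternative-splicing mis-regulation from
    junction-count tables: percent-spliced-in (PSI) estimation with
    length-normalised inclusion/skipping counts, replicate-aware differential
    splicing with a label-permutation test and Benjamini-Hochberg false
    discovery control, microexon (3-33 nt skipped exon) classification,
    odds-ratio based gene-set over-representation and microexon disproportion
    tests, a gapped degenerate motif grammar scanner for RNA-binding protein
    sites (for example the MBNL YGCY family) with splice-site-anchored
    intronic window extraction, cross-dataset overlap and sign-concordance
    statistics, and per-sample mis-splicing burden correlated with numeric
    covariates such as CTG repeat length. A beta-binomial simulator with
    recorded ground truth emulates multi-group splicing datasets, planted
    gene-set effects, planted motifs and dose-response covariates so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    Rsamtools
biocViews: AlternativeSplicing, RNASeq, DifferentialSplicing,
    SequenceMatching, GeneSetEnrichment, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
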