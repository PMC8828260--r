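Package: feederscan
Title: Quantify Mouse Feeder-Cell Contamination in Stem Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to detect and quantify residual mouse embryonic fibroblast
    (feeder cell) contamination in transcriptomic data from human pluripotent
    stem cells. Provides mutually exclusive dual-genome read partitioning with
    a mixing-ratio statistic for mRNA-Seq, a cross-species miRNA clustering
    and cluster-level quantification pipeline that classifies miRNAs as
    species-specific (Type-A/Type-B) or conserved, marker-miRNA and
    misalignment-influenced gene calling by fold-change rules, an exhaustive
    mismatch/edit-distance short-sequence mapper, and a synthetic two-species
    data generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
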