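Package: novelseq
Title: Assembly-Free Discovery of Non-Reference Novel Sequences from Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies DNA sequences that are absent from a reference genome
    directly from noisy long reads, without genome assembly. Candidate reads
    carrying unmapped fragments are quality-filtered and adapter-trimmed,
    refined through a multi-round align-and-subtract loop against the
    reference, screened for contaminants using Kraken2-style taxonomic calls
    with a recomputed confidence score, collapsed into redundancy clusters by
    mutual alignment coverage, and filtered for low-complexity and simple
    tandem repeat content. A split-read caller places novel sequences on the
    reference as single-end (SEP) or both-end (BEP) anchored insertions and
    labels cross-sample sharing. Includes a self-contained seed-and-extend
    pairwise aligner emitting PAF, and a synthetic long-read data generator
    with planted insertions, contaminant spike-ins and truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
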