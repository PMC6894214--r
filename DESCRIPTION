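Package: pangraphr
Title: Genome Graphs from Whole-Genome Multiple Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed genome (pangenome) graphs by collapsing
    whole-genome multiple sequence alignments into shared-sequence nodes.
    Each input genome is a labelled walk through the graph; nodes carry
    per-isolate 1-based coordinates, with negative reversed values
    encoding inversions. Provides co-linear block decomposition input
    (XMFA), a built-in progressive aligner plus wrappers for external
    MSA tools, queries on the graph (sub-sequence and gene extraction,
    coordinate translation between isolates, conserved regions,
    position-based gene homology), GraphML import/export, build
    reports, and a synthetic-genome fixture generator with recorded
    mutation ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
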