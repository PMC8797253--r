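Package: recsplice
Title: Detection of Recursive Splicing Sites and RS-Like Cryptic Exons
    from Total RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects recursive splicing (RS) sites and RS-like cryptic
    exons in long introns from aligned total RNA-seq data.  Builds
    collapsed gene models from a GTF annotation, enumerates AGGT (and
    generalized AGNN) acceptor motifs on gene sense strands, extracts
    splice junctions from CIGAR strings, applies the intron-length /
    mRNA-enrichment / junction-count filtering cascade, scores the
    saw-tooth nascent-transcription coverage signature that
    distinguishes RS sites from unannotated exons, reconstructs and
    scores reconstituted 5' splice sites, and quantifies splicing
    intermediates.  Includes a nascent RNA-seq simulator with planted
    ground truth so every stage is testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    GenomicAlignments,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
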