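Package: polyAterm
Title: Poly(A)-Site Calling and Transcription-Termination Profiling for
    Fission Yeast 3'-End Sequencing and Spike-In ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse transcription termination in fission yeast
    from 3'-end sequencing (3'READS) and spike-in normalized ChIP-seq.
    Calls poly(A) sites (PAS) from aligned reads carrying untemplated
    5' T runs, assigns them to the nearest gene 3' end, updates
    transcriptional 3'-end coordinates, and computes distance and
    read-density statistics with an exact Wilcoxon signed-rank test.
    Implements the spike-in (S. cerevisiae reference chromatin)
    normalization chains for ChIP-seq coverage tracks, multi-anchor
    metagene aggregate profiles with block-confined smoothing, and
    genome-wide Pearson correlation of binned tracks with hierarchical
    clustering. A synthetic-data generator with a recorded truth table
    (planted PAS, global occupancy factor, read-through shift) makes
    every stage testable without deposited sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    graphics,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
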