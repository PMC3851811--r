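Package: mirnome
Title: Composite miRNA Transcriptome Profiling from Small RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates collapsed small RNA sequencing reads into RNA classes by
    hierarchical elimination, builds reference-miRNA and abundant-isomiR
    expression profiles normalised as transcripts per million, classifies each
    miRNA by whether its dominant isomiR equals the canonical mature sequence,
    and screens unannotated reads for potential novel miRNAs with a
    maximum-base-pairing hairpin filter. A synthetic small RNA-seq generator
    with planted ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    ape,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
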