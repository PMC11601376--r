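Package: bxsv
Title: Barcode-Aware Local Assembly for Structural Variant Detection in
    Linked-Read Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects insertions and deletions in the 50-10,000 bp range from
    barcoded linked-read (synthetic long read) alignments, optionally augmented
    with low-coverage long reads. The reference is tiled into overlapping
    segments; for each segment, reads are recruited by fragment barcode
    (including badly aligned mates rescued from a genome-wide read map), locally
    assembled with a diploid-aware de Bruijn graph, and the resulting contigs
    are re-aligned to the reference so that insertions and deletions can be
    read off the alignment CIGAR and written to VCF. Ships a fragment-based
    linked-read and HiFi-like long-read simulator with ground-truth VCF output
    and a breakpoint-matching benchmark evaluator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    Rcpp,
    methods,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    BiocGenerics,
    jsonlite,
    optparse
Config/testthat/edition: 3
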