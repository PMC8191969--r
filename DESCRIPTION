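Package: promtrap
Title: Promoter-Trap Reporter Mapping and Barcode Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for pooled promoter-trap screens of barcoded
    promoterless reporter insertions (TRIP-style assays). Extracts line
    barcodes and genomic flanks from T-DNA junction reads, maps flanks to a
    reference genome with bounded mismatches, calls precise locus-barcode
    pairs, quantifies relative transcription levels from DNA/RNA barcode
    counts, classifies insertions by genomic context and wild-type
    transcriptional status, and computes cohort-level activation statistics.
    Includes a synthetic-data generator producing mini-genomes, transgenic
    cohorts and read libraries with known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
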