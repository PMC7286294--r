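Package: tadapipe
Title: Targeted DamID Transcriptional and Chromatin Profiling Pipeline
Version: 0.1.0
Authors@R: person("tadapipe", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for Targeted DamID (TaDa) experiments: builds the
    GATC restriction-fragment coordinate system from a genome, quantifies
    Dam-fusion over Dam-only log2 signal ratios per fragment, identifies RNA
    polymerase II occupied (transcribed) genes with a permutation false
    discovery rate, compares cell types by replicate-wise ratio subtraction
    with unique-enrichment/depletion classification across developmental
    stages, calls transcription-factor binding peaks as runs of consecutive
    GATC fragments with replicate consensus and proximity-based gene
    assignment, detects chromatin accessibility changes from Dam-only
    (CATaDa) signal, and mines sparse single-cell expression matrices for
    co-expression overlap. Includes a seeded synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
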