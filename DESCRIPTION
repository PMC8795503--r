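Package: txstress
Title: Transcription Stress, GC Skew, and Chromosome Fragility Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying transcription stress and chromosome
    fragility in senataxin (SETX)-deficient cells. Implements
    permutation-based enrichment tests of copy-number changes against
    fragile-site region sets, a transparent run-threshold caller for
    array-CGH log2-ratio tables, RNA polymerase II traveling-ratio and
    promoter-pausing statistics from coverage tracks, GC-skew computation
    and quantile stratification of genes, ChIP/DRIP-qPCR quantification
    (percent input, fold enrichment versus IgG, 2^-ddCt), and a seeded
    synthetic-data generator that emulates the statistical structure of
    the arrays and sequencing data so the whole pipeline is testable
    offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
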