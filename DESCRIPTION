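Package: regulonscope
Title: Regulon Mapping from ChIP-Seq, RNA-Seq, and Circadian Reporter Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for mapping the regulon of a
    light-responsive, clock-controlled transcription factor. Calls
    ChIP-seq binding peaks against a lognormal background model with a
    forward/reverse strand cross-correlation shift filter, assigns peaks
    to genes with strand-aware promoter and downstream windows (including
    double assignment between divergently transcribed genes), integrates
    differential-expression tables to split activated/repressed and
    direct/indirect targets, detects circadian rhythmicity in
    bioluminescence reporter traces by sine-versus-line model comparison
    under the small-sample Akaike criterion, and computes hypergeometric
    gene-set enrichment and light/clock membership partitions. A
    synthetic-data module generates annotated toy genomes, planted-peak
    stranded coverage, expression tables, and damped sinusoidal reporter
    series so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
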