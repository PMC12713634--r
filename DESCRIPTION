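Package: tssenrich
Title: TSS-Proximal Binding Enrichment Analysis for ChIP-seq and RNA-seq Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates transcription-factor ChIP-seq binding with RNA-seq
    differential expression. Implements a sliding-window bin-threshold peak
    caller for aligned tags, classification of genes into up-, down- and
    unchanged groups from a DESeq2-style results table, construction of
    strand-aware windows around transcription start sites, per-group
    peak-overlap frequencies with pairwise two-proportion Z-tests, and a
    seeded synthetic-data generator that plants binding sites preferentially
    near one group's TSSs so the whole pipeline can be exercised and
    validated without external data. Small statistics utilities (Welch
    t-test, qPCR delta-Ct Z-score normalization) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
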