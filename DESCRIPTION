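Package: cistromeCT
Title: Cistrome-Transcriptome Integration for Transcription Factor
    Regulatory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates transcription factor cistromes (ChIP-seq binding
    sites, ATAC-seq accessible regions) with transcriptome readouts.
    Annotates peaks to genes within a configurable window (default 100 kb),
    stratifies links by distance zone and chromatin state, tests
    cistrome-gene/DEG overlaps with an upper-tail hypergeometric test,
    computes distance-weighted cistrome-transcriptome (wt-C-T) scores with
    permutation significance, classifies oppositely regulated gene-set
    enrichment terms by delta-NES, ranks co-enriched factors from
    cistrome-similarity tables, and screens coregulators by the change
    between Pearson and first-order partial correlations (delta.corr).
    Includes a seeded synthetic-data generator that emulates the
    statistical structure of the expected inputs so every stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    stats,
    utils,
    tools,
    methods,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
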