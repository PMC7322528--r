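Package: mchron
Title: Time-Lagged Multi-Omics Association and Chromatin Regulatory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for multi-omics time courses of cellular
    differentiation (chromatin accessibility, transcriptome, proteome,
    ChIP). Implements directional time-lagged cross-layer association
    testing with Fisher's exact test and a central-dogma flow filter,
    permutation-null transcription-factor activity scoring from
    accessibility at motif sites, ChIP peak consensus, co-occupancy and
    regulatory-group analysis, chromatin-bound interactome (ChIP-SICAP
    style) enrichment scoring, peak-to-gene assignment, and seeded
    synthetic multi-omics generators with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
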