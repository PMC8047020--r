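Package: tacomics
Title: Trans-Omics Analysis of Single-Cardiomyocyte Time-Course Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-course single-cell RPKM expression data
    from pressure-overload (TAC) mouse hearts: cell quality control, one-way
    ANOVA screening for temporally regulated genes, hierarchical clustering of
    expression profiles with SSE-based cluster-count selection, fold-change
    marker ranking, marker-gene high/low cell partitioning with subgroup
    differential expression, marker-correlation gene programs, MCODE-style
    dense-module detection on gene-gene association networks, and transcription
    factor enrichment from ChIP-seq peak sets via a two-tailed Fisher's exact
    test over transcription start site windows. Includes a synthetic-data
    generator emulating the study design so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    Matrix,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
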