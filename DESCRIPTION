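Package: ctcProfiler
Title: Single-Cell qPCR Profiling of Circulating Tumor Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-cell qRT-PCR profiling of
    circulating tumor cells (CTCs) captured from cancer patient blood and
    measured on microfluidic dynamic arrays. Implements measurement-level
    quality control of cycle-threshold (Ct) readings, chip-level gene
    exclusion, RNA-integrity gating on reference genes, rule-based
    CTC/leukocyte classification from keratin and CD45 expression, balanced
    subsampling, reference-panel negative delta-Ct normalization with
    per-gene median centering, detectability-based gene selection, and
    hierarchical clustering with low-expression imputation of missing
    values, plus cluster-composition reporting. A synthetic-data module
    generates chip-like Ct datasets with planted cell populations and known
    ground truth so every stage is testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    ape,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
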