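Package: scpipeline
Title: Single-Cell RNA-Seq Profiling: Cell Types, Signatures and Regulatory Driving Forces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for single-cell RNA-seq expression profiles
    (FPKM/TPM scale) from heterogeneous cell populations. Provides gene
    pre-filtering by expression abundance and a cell specificity index,
    per-sample z-score and trimmed-mean normalization with quality-control
    summaries, hierarchical clustering of cells with automatic threshold
    selection and permutation significance, per-cluster one-tailed differential
    expression with automatic Welch/Wilcoxon selection and false discovery rate
    control, cell-type enrichment via one-tailed Fisher's exact test,
    rank-aggregation marker validation with ROC/AUC, logistic-regression
    ranking of cell-type signature genes, first-order conditional-dependence
    inference of transcriptional regulatory networks, and transcription-factor
    importance ranking by six centrality and disruption metrics. Includes a
    synthetic-data generator with planted ground truth for every stage and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    e1071,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
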