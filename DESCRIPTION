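Package: lungatlas
Title: Single-Cell Immune Atlas Pipeline for the Developing Mouse Lung
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable, tested implementation of a Smart-seq2 single-cell
    RNA-seq analysis pipeline for perinatal mouse lung immune cells: read-depth
    and gene-detection quality filters with doublet-cluster exclusion and full
    cell accounting, counts-per-million normalization with a log10 pseudocount,
    per-mouse Fano-factor feature selection, PCA, symmetrized kNN graphs,
    Leiden community detection and t-SNE, marker-panel cluster annotation and
    dot-plot summaries, a same-mouse versus different-mouse pair-distance test
    for replicate batch variation, one-vs-rest Kolmogorov-Smirnov differential
    expression ranking, second-order kNN-graph count smoothing, diffusion
    pseudotime with scalar-potential attractor detection on a grid over the
    embedding, and developmental abundance quantification. Ships a synthetic
    atlas generator (negative-binomial counts, eight mice across four
    perinatal timepoints, fifteen immune populations, doublets and low-depth
    cells) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
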