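Package: scEvalMetrics
Title: Multi-Level Evaluation Metrics for Single-Cell Embedding and Clustering Benchmarks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation toolkit for single-cell chromatin-accessibility and
    related clustering benchmarks. Scores cell embeddings (silhouette widths,
    fraction of negative silhouettes, cluster-level local inverse Simpson
    index), shared-nearest-neighbor graphs (proportion of weakly connected
    cells, Geary's C), and predicted partitions against ground-truth cell
    types (adjusted Wallace indices with per-class and per-cluster
    decompositions, adjusted Rand index and its class-size-debiased variant,
    mutual information, variation of information, evenness). Summarizes
    resolution sweeps as normalized areas under metric-versus-cluster-number
    curves with a robust heatmap transform, quantifies seed stability and
    library-size bias in latent spaces, and scores paired cross-modality
    integrations (FOSCTTM). A seeded synthetic-data generator produces
    Gaussian-mixture embeddings, library sizes, partition perturbations and
    paired modalities so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
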