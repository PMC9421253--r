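Package: pcpgHet
Title: Single-Nucleus Transcriptome Heterogeneity Analysis for
    Pheochromocytoma and Paraganglioma
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to dissect intra- and inter-tumoral transcriptome
    heterogeneity in single-nucleus RNA-seq of pheochromocytoma and
    paraganglioma (PCPG) cohorts: per-library quality filtering,
    log-normalization, variable-gene selection, PCA and shared
    nearest-neighbor graph clustering with marker-based cell-type
    annotation; expression-inferred copy-number profiles (reference
    centering, 101-gene genomic smoothing, three-state HMM segmentation);
    per-sample non-negative matrix factorization with extraction of
    top-gene transcriptional programs, cohort-wide module scoring,
    correlation/Ward clustering of programs into metaprograms, and
    mutation-group score comparison; elastic-net logistic-regression
    similarity mapping of query cells onto a labeled reference. Includes
    a fully ground-truthed synthetic cohort generator that plants cell
    type mixtures, shared expression programs and chromosomal dosage
    segments, and an end-to-end pipeline driver with seed management.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    SingleCellExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    igraph,
    jsonlite,
    yaml
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
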