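Package: relapsescore
Title: Single-Cell Drug-Sensitivity Scoring and Relapse-Risk Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies individual leukemic blasts as prednisone-sensitive or
    prednisone-resistant from single-cell RNA-seq UMI counts, using gene-module
    scores computed against expression-bin-matched control genes, and
    aggregates the per-cell calls into patient-level relapse-risk predictions.
    Includes the supporting analyses (first-principal-component continuum
    score, Wilcoxon differential expression between the two cell states,
    gene-to-score Spearman correlation, and pseudobulk construction by
    complete or equal-contribution downsampled pooling), a negative-binomial
    synthetic-cohort generator with a latent per-cell resistance continuum for
    validation, and readers/writers for Matrix Market count matrices and CSV
    result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
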