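Package: crossfc
Title: Cross-Assay Harmonization of Paired Expression Fold-Changes for
    Recurrence Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Combines paired pre/post-chemotherapy transcriptomic cohorts
    measured on heterogeneous platforms (bulk RNA-seq, NanoString,
    microarray, pseudobulked single-cell RNA-seq) into a single modeling
    cohort on the patient-level log2 fold-change scale.  Provides
    normalization and counting-mode aggregation, cross-assay concordance
    diagnostics, limits-of-detection estimation from double-assay designs,
    bootstrap predictive-frequency feature selection, regularized
    classifiers of progression-free-survival class with stratified
    hold-out evaluation, survival-based external validation (Cox,
    Kaplan-Meier), focal-gene topological-overlap network contrasts, and
    a synthetic multi-assay cohort generator with planted ground truth
    for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    Matrix,
    glmnet,
    e1071,
    survival,
    cluster,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
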