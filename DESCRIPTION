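Package: rppasig
Title: Biomarker Signature Discovery from RPPA Tumor Profiles with
    Cross-Modality Validation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers and validates minimal protein biomarker signatures of
    drug response from reverse-phase protein array (RPPA) profiles of
    patient-derived xenograft (PDX) cohorts. Implements unsupervised Ward
    bi-clustering of median-centered log2 expression matrices, in-vivo
    response calling from tumor growth records with exact binomial confidence
    intervals and Cramer's V covariate association, a fold-change threshold
    sweep with support vector machine evaluation by precision-recall and ROC
    curves, transfer of protein-trained classifiers to matched mRNA data,
    fold-change concordance against external cohorts with permutation
    controls, and per-section immunohistochemistry positivity scoring with a
    two-marker difference metric. A synthetic cohort generator with planted
    cluster structure makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pheatmap,
    optparse
biocViews: Proteomics, Classification, Clustering, BiomedicalInformatics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
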