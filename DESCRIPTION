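Package: abgrade
Title: Molecular Grading of Breast Cancer Tumors from Antibody Microarray Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for recombinant antibody (scFv) microarray protein
    profiling of breast cancer tumor tissue graded by Nottingham histological
    grade. Implements replicate aggregation with a coefficient-of-variation rule,
    limit-of-detection filtering against PBS negative-control spots, PCA-based
    outlier flagging, semiglobal normalization on low-CV reference analytes,
    rank-based differential protein expression with false discovery rate control,
    leave-one-out cross-validated linear support vector machine classification of
    histological grade with ROC/AUC summaries, SVM-based backward elimination of
    antibodies into condensed biomarker signatures tracked by a Kullback-Leibler
    classification error, and three re-classification models that resolve
    heterogeneous grade 2 tumors into grade-1-like, grade-3-like, or indeterminate
    calls (a frozen-model decision-value grey zone and two bootstrap tally
    schemes). A seeded synthetic-data generator reproduces the statistical
    structure of the assay for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    readxl,
    pROC,
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
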