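Package: CausalPanel
Title: Causal-Metric Biomarker Panel Selection for Case/Control Diagnosis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects small diagnostic biomarker panels from antibody-array
    style case/control reactivity matrices using a pairwise causal metric
    (sensitivity-times-specificity scoring of gamma-binarized analytes with
    eligibility gating and case-sample relatedness sets), alongside a
    chi-square univariate baseline, and evaluates panels with a
    leave-one-out cross-validated classification pipeline (five classifier
    families; AUC and sensitivity at fixed specificity). Includes a
    synthetic case/control generator with planted informative analytes for
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    nnet,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, BiomedicalInformatics,
    ImmunoOncology
RoxygenNote: 7.3.3
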