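Package: nestedSelect
Title: Nested Feature Selection and Classification for Case/Control RNA-Seq Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a reproducible blood-transcriptome case/control
    classification workflow for multi-site bulk RNA-seq cohorts: count
    preprocessing (biotype and low-expression filtering, median-of-ratios
    size factors, independent filtering, a closed-form variance stabilizing
    transformation, control-anchored site-batch removal and covariate
    residualisation), a per-gene negative-binomial Wald differential
    expression baseline, nested random-forest importance ranking feeding a
    gradient-boosted classifier across a sweep of feature-set sizes,
    selection-frequency stability analysis, classification metrics and
    endophenotype predicted-probability comparisons. A multi-site synthetic
    cohort generator with planted signal provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    DESeq2,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, DifferentialExpression, RNASeq, FeatureExtraction
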