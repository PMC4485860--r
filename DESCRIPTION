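Package: drugRFE
Title: Drug Sensitivity Classification from Baseline Gene Expression by
    Recursive Feature Elimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds per-drug sensitive/resistant classifiers from baseline
    gene-expression profiles of cancer cell lines. Continuous drug response
    (activity area or IC50) is z-scored and discretized at +/-0.8 SD into
    sensitive, intermediate and resistant classes; genes are ranked by
    SVM-RFE (with F-score and random-forest baselines); a kernel SVM is
    tuned by repeated stratified 10-fold cross-validation over the cost and
    gamma grids; a second cohort is harmonized by empirical-Bayes batch
    adjustment and used for independent transfer validation (accuracy,
    ROC/AUC, Welch t-test); agreement between two cohorts' gene rankings is
    scored by binned Fisher's exact overlap tests. A synthetic-data module
    generates paired cohorts with planted informative genes, batch effects
    and oppositely oriented response readouts so every stage can be checked
    against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    e1071,
    randomForest,
    sva,
    jsonlite,
    yaml,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
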