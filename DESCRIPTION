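Package: caflncnet
Title: Differential lncRNA Discovery and Network-Based Function
    Prediction in Cancer-Associated Fibroblasts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end workflow for identifying long non-coding RNAs
    (lncRNAs) differentially expressed between cancer-associated
    fibroblasts (CAF) and normal ovarian fibroblasts (NOF) on log2
    microarray expression data, assessing their joint predictive power
    with SMOTE class rebalancing and repeated discovery/validation
    resampling of logistic-regression, random-forest and linear-SVM
    classifiers, and predicting their functional roles by
    guilt-by-association: transcription-factor (TF) enrichment builds a
    context-specific TF-lncRNA / TF-target-gene regulatory network,
    per-TF hierarchical clustering with multiscale bootstrap resampling
    extracts co-regulatory modules, and hypergeometric pathway
    enrichment of each module's coding genes transfers metastasis
    pathway annotations to its lncRNA members. A seeded synthetic-data
    generator with planted ground truth makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    e1071,
    fgsea,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
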