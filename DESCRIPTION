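Package: stemsig
Title: Pan-Cancer Stemness Signatures and Immunotherapy Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a pan-cancer stemness gene signature from panels of
    single-cell RNA-seq datasets and uses it to predict immune-checkpoint
    inhibitor response in bulk tumor cohorts. Implements a gene-counts based
    per-cell stemness score, per-dataset selection of stemness-correlated
    (Gx) and malignant-upregulated (Gy) genes with geometric-mean
    aggregation across datasets, single-sample gene-set enrichment scoring
    of bulk tumors, a kernel Naive Bayes response classifier with survival
    stratification, and aggregation of CRISPR immune-screen z-scores to
    rank candidate therapeutic targets. Ships synthetic-data generators
    with planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    sva,
    tibble,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
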