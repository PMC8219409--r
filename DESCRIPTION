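Package: ptbrisk
Title: Entropy-Based Feature Selection and Risk Classification for
    Preterm-Birth Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for preterm-birth (PTB) risk classification from
    tabular obstetric cohort data: schema-validated CSV ingestion, mean/mode
    imputation, supervised and unsupervised discretization, an entropy-notion
    feature-selection filter (per-partition information gain with a
    range-based threshold and subset union), SMOTE class balancing, a
    stratified 70/30 evaluation harness for decision-tree, logistic-regression
    and support-vector classifiers, and a seeded synthetic-cohort generator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    withr,
    rpart,
    e1071
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
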