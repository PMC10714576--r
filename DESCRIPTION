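Package: immunoscore
Title: Immune-Status Scoring for Healthy Adults from Complete Blood Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Evaluates the immune status of healthy adults from routine
    complete blood count (CBC) panels. Raw records are screened with
    inflammation filters (procalcitonin and leukocyte reference ranges),
    fifteen immune-related indexes are normalized with a piecewise-Gaussian
    "three-platform" sigmoid fitted on the log scale, immune-status groups
    are discovered with an expectation-maximization Gaussian mixture model,
    per-index weights are derived from averaged tree-ensemble feature
    importances over repeated train/test splits, and a weighted-sum
    immunity score is referenced against a cubic age curve to classify
    individuals as healthy or sub-healthy. Includes a synthetic-cohort
    generator with age-correlated log-normal indexes for end-to-end
    validation, internal cluster-validity indices (silhouette,
    Calinski-Harabasz, Davies-Bouldin), and a reproducible pipeline
    driver with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    cluster,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
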