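Package: prrtselect
Title: Two-Level Machine-Learning Selection of PRRT Eligibility Predictors
    in Neuroendocrine Neoplasms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts eligibility for peptide receptor radionuclide therapy
    (PRRT) in metastatic neuroendocrine neoplasms from clinical, pathological,
    immunohistochemical and laboratory features, at both the lesion and the
    patient level, and ranks predictors with an F1-weighted
    permutation-importance consensus framework. Lesion radiotracer uptake
    ratios are graded on the semiquantitative Krenning scale; a patient is
    PRRT-suitable when their least active lesion still scores Krenning 3-4.
    Includes a synthetic two-level cohort generator with planted covariate
    effects, retrospective missingness and class imbalance; a benchmark grid
    of random-forest, gradient-boosting and regularized-linear classifiers
    over variable-group subsets with optional SMOTE oversampling; stabilized
    permutation importance aggregated across models by normalized F1; and
    nonparametric confirmation of selected features (Mann-Whitney,
    Kruskal-Wallis, chi-square).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
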