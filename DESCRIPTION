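Package: edlama
Title: Optimized Explainable Prediction of Left-Against-Medical-Advice
    Emergency Department Visits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting and explaining "left against medical
    advice" (LAMA) dispositions in emergency departments from triage and
    demographic data.  Provides an adaptive tabu simulated annealing (ATSA)
    optimizer for hyperparameter tuning of gradient-boosted classifiers
    over mixed integer/float search spaces, sequential forward/backward
    wrapper feature selection, K-nearest-neighbour imputation with an
    artificial-missingness MAPE validation protocol, fold-wise class
    rebalancing with leakage auditing, Shapley-style additive attribution
    summaries and interaction grids, a synthetic ED-visit generator with a
    configurable planted outcome signal, and a configuration-driven
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    rpart,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
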