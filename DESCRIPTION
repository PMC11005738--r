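Package: promflux
Title: Promoter-Combination Design and Ensemble Regression for Pathway Flux Balancing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for machine-learning-aided balancing of a heterologous
    metabolic pathway by combinatorial promoter engineering. Represents a
    combinatorial promoter library (one promoter per pathway gene), encodes
    designs as one-hot features, computes coupon-collector sampling depth for
    library coverage, curates colorimetric screening data into balanced
    training sets, fits a greedy forward-selected ensemble of thirteen base
    regressors to predict product titer, ranks the full combinatorial design
    space, and ships a mechanistic series-bottleneck pathway simulator with an
    epistasis classifier so the whole pipeline is testable without wet-lab
    data. Includes Michaelis-Menten helpers (double-reciprocal fits, catalytic
    efficiency, fold change) for enzyme kinetics bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    caret,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
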