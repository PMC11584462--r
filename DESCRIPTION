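Package: dendrogap
Title: Machine-Learning Gap Filling for Dendrometer Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to process half-hourly point-dendrometer stem-radius
    records and to impute long data gaps in individual trees. Covers quality
    control of raw sensor data (jump detection with a frost guard, linear
    interpolation of short gaps), extraction of cumulative growth and tree
    water deficit with the zero-growth model, construction of purely temporal
    predictor matrices screened for multicollinearity, and gap filling with
    early-stopped gradient-boosted regression trees alongside spline and
    tree-network baselines. Includes a seasonal artificial-gap benchmark
    harness with permutation feature importance and nonparametric method
    comparison, plus a synthetic dendrometer simulator so the whole pipeline
    can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    caret,
    glmnet,
    jsonlite,
    lhs,
    ranger,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
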