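Package: keyclock
Title: Diurnal Typing Regularity, Passive Sleep Estimation, and Cognitive
    Performance Prediction from Smartphone Keystroke Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates diurnal typing patterns and sleep from sparse smartphone
    keystroke metadata by smoothing days-by-hours activity matrices with a
    toroidal graph-regularized singular value decomposition, labels one
    contiguous sleep block per relative 24 hour period, engineers typing,
    phone-orientation, and regularity features, and predicts practice-adjusted
    digital Trail-Making-Test part B completion times with interpretable
    models (Lasso, support vector regression, k-nearest neighbours, random
    forest) selected by a mutual-information filter under subject-wise
    cross-validation.  Includes a synthetic-cohort generator with planted
    ground truth for recovery testing, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    cluster,
    glmnet,
    e1071,
    ranger,
    caret,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
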