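Package: fluidsim
Title: Federated Label Distillation for Secondary-Pharmacology QSAR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates and evaluates federated learning by label distillation
    for binary activity (QSAR) classification in secondary pharmacology.
    Partner-private "teacher" classifiers label a large shared pool of
    unlabeled molecules; predictions are consolidated across partners,
    filtered by reliability (chemical-space proximity), ranked by
    decidability (prediction confidence), and distilled into a balanced
    federated training set on which global "student" models are trained and
    optionally refined with internal data. Includes SMILES standardization
    and Morgan-fingerprint featurization, a configurable synthetic
    multi-partner world generator with temporal splits and class-imbalance
    control, an eleven-architecture model zoo with seeded hyperparameter
    search and repeated cross-validation, three-domain
    applicability/reliability/decidability scoring, confusion-matrix metrics
    (balanced accuracy, MCC), joint chemical-space embedding, and a
    config-driven end-to-end experiment runner with reproducible outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    pROC,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
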