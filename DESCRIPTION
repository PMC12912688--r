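Package: nocibench
Title: Benchmarking Classical and Transfer-Learning Models for Intraoperative Nociception Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible head-to-head benchmark of classical supervised
    models (L1-regularised logistic regression selected by AIC, random
    forests) against a personalised temporal-convolutional transfer-learning
    model for intraoperative nociception detection. Provides a synthetic
    multi-surgery cohort generator with event-coupled autonomic features and
    drug-dosing chronology covariates, leave-one-surgery-out evaluation with
    AUROC/AUPRC, bootstrap confidence intervals and paired Wilcoxon tests,
    probability calibration (Platt, isotonic, quantile-binned expected
    calibration error), gated and meta-learner ensembles, permutation
    importance, and analytic inference-cost accounting (multiply-accumulate
    operations and parameter memory).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    glmnet,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
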