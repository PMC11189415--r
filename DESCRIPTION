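Package: rptanx
Title: Anxiety-Level Prediction from Reward/Aversion Judgment Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a complete analysis pipeline that predicts state
    anxiety levels (STAI-S) from a small set of interpretable judgment
    variables derived from a short picture rating task, together with
    demographic and contextual survey variables. Relative preference theory
    (RPT) features are extracted per participant from the mean, variance and
    Shannon entropy of positive and negative ratings via value, limit and
    tradeoff curve fits. Anxiety classes are predicted with random forest and
    balanced random forest classifiers, calibrated against a permutation
    null, with normalized Gini relative importance and proximity-based
    multidimensional scaling. Mediation (Baron-Kenny with Sobel test) and
    moderation (interaction partial F-test) models quantify how contextual
    variables interact with judgment variables, and nonparametric tests
    summarise group differences. A synthetic-cohort generator with a latent
    anxiety trait makes every stage testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    randomForest,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
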