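Package: wakemark
Title: Metabolomic Biomarker Discovery for Acute Sleep Deprivation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for discovering and validating
    plasma metabolomic biomarkers of acute sleep deprivation from untargeted
    LC-MS feature tables sampled across extended wakefulness. Covers
    left-censored imputation and median normalization, per-participant and
    group-level linear and 24-hour cosinor trend characterization, a
    knowledge-based a priori feature filter (homeostatic, non-circadian
    features), three-stage random-forest variable selection, hold-out
    classification of well-rested versus sleep-deprived samples and
    regression of time since wake with exact binomial confidence intervals
    and ROC analysis, and mixed-model validation of biomarker recovery after
    a night of sleep. Includes a synthetic-data generator emulating the
    constant-routine and matched-control study designs so every stage is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    rpart,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
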