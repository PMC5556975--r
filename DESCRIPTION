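Package: proshift
Title: Response Shift Detection in Patient-Reported Outcomes with Regression Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects response shift (recalibration and reprioritization) in
    longitudinal patient-reported outcome data using least-squares regression
    trees with surrogate splits, in the style popularised for quality-of-life
    research on dentine hypersensitivity. Provides a from-scratch CART engine
    (improvement-maximising binary splits, fraction-based stopping rules,
    surrogate splits for missing predictors, ten-fold cross-validated risk and
    1-SE cost-complexity pruning), variable-importance scoring over primary and
    surrogate roles, an operationalisation layer that classifies recalibration
    against a minimally important difference and reads reprioritization from
    importance-rank changes, design-based then-test and ideals recalibration
    statistics, and a seeded generator of DHEQ-like two-timepoint trial cohorts
    for testing the whole pipeline.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
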