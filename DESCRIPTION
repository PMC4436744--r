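Package: dietquality
Title: Diet-Quality Scoring and Population-Ratio Analysis for Randomized
    Nutrition Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing diet quality in longitudinal randomized
    trials that collect repeated multi-day food records. Computes Healthy
    Eating Index 2005 component and total scores and Whole Plant Food
    Density from coded food-group equivalents, estimates visit- and
    arm-level mean densities by the population-ratio method with bootstrap
    standard errors, tests for an overall treatment effect with a
    permutation test on the Euclidean distance between the arms' vectors of
    visit-specific population ratios, and supports intent-to-treat analysis
    through predictive-mean-matching multiple imputation with Rubin's
    pooling rules. Includes noncentral-t power calculations for two-sample
    designs and a synthetic-trial generator (stratified permuted-block
    randomization, multi-day intake records, informative withdrawal) for
    validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
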