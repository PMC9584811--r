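Package: intertemporal
Title: Adaptive Intertemporal-Choice Titration, Anomaly Scoring and
    Country-Level Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for eliciting and analysing temporal discounting with a
    short adaptive titration instrument. Encodes the contingent branching of
    a three-set staircase (small gains, losses, large gains) plus four
    anomaly items (present bias, subadditivity, delay and speedup framing),
    derives simplified indifference points, and converts response patterns
    into a 0-19 discounting score with flags for five intertemporal choice
    anomalies and their mirror inconsistencies. Includes a parametric
    respondent simulator (exponential, hyperbolic and quasi-hyperbolic
    agents with magnitude, sign, framing and subadditivity mechanisms and a
    logistic choice rule), pre-registered quality-control exclusion filters,
    and country-level aggregation: DerSimonian-Laird random-effects
    meta-analysis with prediction intervals, method-of-moments
    meta-regression, logit-scale pooling of anomaly proportions, and
    between/within-country variance partition.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    purrr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
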