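Package: covermeta
Title: Random-Effects Meta-Analysis of Cover Crop Effects on Nitrate
    Leaching and Water Drainage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for random-effects meta-analysis of paired cover-crop versus
    bare-fallow field comparisons, built around the natural-log response ratio
    effect size with nonparametric (replicate-count) variance weights. Provides
    observation-table ingestion with the inclusion rules used in cover-crop
    leaching syntheses, Cochran Q and I-squared heterogeneity statistics,
    DerSimonian-Laird tau-squared, subgroup (moderator) within/between
    Q-partitioning, the Begg-Mazumdar rank-correlation publication-bias test
    with funnel-plot data export, single-covariate REML meta-regression, and a
    synthetic observation-table generator with known truth for end-to-end
    verification of every pipeline stage.
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
    tools,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
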