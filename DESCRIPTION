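Package: metaharvest
Title: Meta-Analysis of Forest Harvesting Effects on Ecosystem Carbon Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of harvested versus reference forest
    stands across ecosystem carbon pools (live trees, snags, understory
    vegetation, coarse woody debris, forest floor, mineral soil). Computes
    log response ratio effect sizes with delta-method standard errors,
    partitions heterogeneity into within- and between-group Q statistics
    with an iterative hierarchical moderator-selection procedure, fits
    weighted (inverse-variance, DerSimonian-Laird or REML tau-squared) and
    unweighted mixed-effects meta-regressions with nonparametric case
    bootstrap confidence intervals, and selects time-since-treatment trend
    models by AIC among linear, cubic and natural-spline families. Includes
    a synthetic-data generator with known per-stratum effects,
    between-study heterogeneity and recovery trajectories for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    metafor,
    lme4,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
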