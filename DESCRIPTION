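Package: pftshift
Title: Stacked Species Distribution Modelling of Plant Functional Type
    Shifts Under Climate Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An ensemble species distribution modelling (SDM) workflow for
    projecting climate-driven transitions of plant functional types (PFTs).
    Generates virtual landscapes and virtual species with known niches,
    screens predictors for multicollinearity, fits replicated
    presence/pseudo-absence models with four pluggable learners, evaluates
    them by AUC, the Continuous Boyce Index and a calibration statistic,
    binarizes ensembles with maxSSS thresholds and algorithm-agreement
    voting, stacks species into PFT richness and presence maps, and derives
    dominant-PFT maps, transition flows, latitude-altitude range shifts,
    Riitters-style moving-window fragmentation classes, and ANOVA variance
    partitions of projection uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    mgcv,
    glmnet,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
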