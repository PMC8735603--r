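Package: rarescape
Title: Ensembles of Small Models for Rare Species Distributions and
    Spatial Richness Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits presence-background species distribution models for rare
    species with the Ensemble of Small Models (ESM) strategy: all bivariate
    predictor combinations are fitted with a penalized maximum-entropy-style
    logistic learner and a random forest, scored by cross-validated Somers' D,
    and averaged with skill-proportional weights. Continuous suitability maps
    are binarized at the maximum sensitivity-plus-specificity threshold and
    stacked into species richness surfaces, overall and by guild. Pixel-level
    spatial concordance between two richness surfaces is quantified with the
    local bivariate Lee's L statistic and classified by a Monte Carlo
    permutation test. A synthetic landscape generator (Gaussian random
    fields with controlled cross-correlation, plot networks, and virtual
    species with known bivariate responses) makes the whole pipeline testable
    without external data. Remote-sensing predictor helpers (EVI2, NDWI,
    BSI, PALSAR HV/HH ratio, annulus topographic position index,
    standardization, and pairwise-correlation screening) are included.
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
    glmnet,
    jsonlite,
    Matrix,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
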