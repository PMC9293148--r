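Package: icehab
Title: Ensemble Habitat Models and Climate-Sensitivity Ranking for
    Ice-Obligate Seals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Balanced-bootstrap ensemble habitat modelling for
    presence-absence records of ice-obligate Antarctic seals, with
    collinearity screening by variance inflation factor, a three-member
    ensemble (random forest, boosted regression trees, and an in-package
    L1-regularised maximum-entropy learner) tuned per bootstrap by
    cross-validation, cross-model permutation and split-gain variable
    importance, and the expert-score-weighted change importance product
    that ranks environmental covariates by their climate-sensitive
    influence on breeding habitat. Includes a synthetic presence-absence
    generator with known drivers, controlled collinearity and severe
    class imbalance so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    ranger,
    stats,
    utils,
    xgboost
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
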