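Package: ensembleSDM
Title: Ensemble Species Distribution Modelling with Collinearity
    Screening and Habitat-Change Accounting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for ensemble species distribution
    modelling: occurrence cleaning and spatially constrained
    pseudo-absence sampling, two-stage collinearity screening of
    environmental predictors (pairwise Pearson correlation followed by
    stepwise variance-inflation-factor elimination), five base learners
    (adaptive regression splines, boosted trees, multilayer perceptron,
    random forest, support vector machine) combined by skill-weighted
    averaging, first-principles AUC and true-skill-statistic evaluation
    under repeated stratified cross-validation, suitability mapping with
    four-class reclassification and area accounting, and scenario-based
    range-change analysis. A virtual-species simulator generates
    autocorrelated climate-like rasters with a known suitability truth so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    e1071,
    nnet,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
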