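Package: enmpipe
Title: Ensemble Environmental Niche Modeling for Climate-Change Range Forecasts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable pipeline for ensemble environmental niche
    modeling (species distribution modeling) of mountain ungulates under
    climate change. Covers occurrence thinning and train/test splitting,
    background sampling inside a 95% minimum convex polygon, terrain
    predictors (terrain ruggedness index, slope, aspect, distance to escape
    terrain and riparian areas), collinearity pruning, five presence/background
    model families (stepwise GLM, MARS, boosted regression trees, random
    forest, and a Maxent-style penalized logistic model) behind one
    fit/predict contract, sensitivity-equals-specificity thresholding,
    AUC/TSS evaluation, model- and GCM-agreement consensus maps, and
    stable/gain/loss change accounting in square kilometers. A virtual-species
    landscape generator supplies a mountainous DEM, elevation-correlated
    bioclim layers, future-scenario deltas, and occurrences with known truth
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    randomForest,
    xgboost,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
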