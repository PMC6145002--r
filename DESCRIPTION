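Package: enmdiv
Title: Ensemble Niche Models and Diversity Change Under Climate Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible workflow for stacked species distribution
    modelling under climate-change scenarios: variance-inflation-factor
    screening of environmental covariates, per-species niche models fitted
    with four algorithm families (GLM, boosted regression trees, random
    forests, support vector machines), evaluation by AUC and the true skill
    statistic, ensemble forecasts across circulation-model and emission
    pathway members, binarisation at the sensitivity-specificity equality
    threshold, a distance-based dispersal filter for isolated range patches,
    and alpha/beta diversity summaries on a coarse grid: species richness
    and its change, paired tests, local contributions to beta diversity
    (LCBD) with a permutation null, and the Baselga-family decomposition of
    Jaccard dissimilarity into replacement and nestedness with ternary-plot
    coordinates. A virtual-species simulator with known niches provides
    ground truth so every stage can be validated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    randomForest,
    e1071,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
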