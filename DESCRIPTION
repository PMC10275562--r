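Package: evospeed
Title: Eco-Evolutionary Simulation and Model Selection for the Evolutionary Speed Hypothesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially explicit eco-evolutionary simulation of clade
    diversification on a dynamic gridded landscape, with four competing
    population-divergence models (time-only, temperature-dependent,
    body-size-dependent, and combined), a multidimensional biodiversity
    summary-statistic suite (phylogenetic tip rates, assemblage metrics,
    trait distributions, tree shape), Sobol-sequence experiment design,
    supervised-classification model selection with Cohen's kappa weighted
    model-averaged support, and a random-effects meta-analysis of Spearman
    correlations as the correlative baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    jsonlite,
    MASS,
    rpart,
    randomForest,
    xgboost,
    e1071,
    nnet,
    metafor
Suggests:
    testthat (>= 3.0.0),
    picante
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
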