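Package: thermostab
Title: Sequence-Based Prediction of Protein Melting Temperatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for predicting protein thermal stability (melting
    temperature, Tm) from amino acid sequence. Computes a large battery of
    sequence-derived descriptors (composition families, CTD,
    autocorrelation, sequence-order and quasi-sequence-order, pseudo amino
    acid composition, conjoint triads, a windowed dipeptide block, a
    six-group physicochemical block and a ProtParam-style global parameter
    block), trains gradient-boosted regression tree ensembles, performs
    recursive feature elimination with and without an inner
    cross-validation loop, and evaluates predictions with Pearson
    correlation, RMSE, MSE, MAE, R-squared and a three-class Tm binning.
    Includes a synthetic-data generator with planted descriptor signals for
    end-to-end testing and a command-line pipeline for proteome-scale
    batch prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr,
    xgboost
Suggests:
    e1071,
    nnet,
    randomForest,
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
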