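Package: oilauth
Title: Ambient Mass-Spectrometry Authentication of Edible Oils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting and quantifying multi-species
    adulteration of camellia seed oil from ambient-ionisation
    high-resolution mass spectrometry (SICRIT-HRMS) full-scan series.
    Provides mzXML input/output, a synthetic spectrum simulator for the
    five-oil adulteration design, dynamic m/z binning with five-statistic
    temporal aggregation and total-ion-chromatogram shape descriptors,
    feature-importance-driven bin refinement (ANOVA F, mutual information,
    random-forest importance, Pearson correlation), PCA/UMAP feature
    representations, five qualitative classifiers and a one-dimensional
    convolution-attention-MLP quantifier, and chemometric evaluation
    (accuracy/precision/recall/F1/AUC, R2/RMSE/RPD) with repeated-run
    statistics and blind-set confusion ledgers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    mzR,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    cluster,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
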