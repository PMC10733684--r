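Package: nirconfound
Title: Confounder-Controlled Machine Learning for Near-Infrared Spectra of
    Tissue-Engineered Constructs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and controlling the confounding effect of
    non-neotissue constituents (scaffold peptide conjugation, growth factors,
    lysis buffer) on machine-learning assessment of tissue-engineered
    constructs from diffuse-reflectance near-infrared spectra. Provides a
    spectral data model with CSV readers and writers, Savitzky-Golay
    derivative preprocessing, a synthetic-data generator emulating the study
    design, nine fixed-hyperparameter classifiers behind a uniform contract,
    stratified k-fold evaluation of constituent detectability, construction
    of deliberately confounded and propensity-score-matched training sets,
    paired controlled-versus-uncontrolled model comparison, and Monte Carlo
    cross-validation with Day-7 undersampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    e1071,
    glmnet,
    randomForest,
    rpart,
    signal,
    stats,
    utils,
    xgboost
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
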