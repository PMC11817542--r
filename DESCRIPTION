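Package: misinfonet
Title: Classifying Trustworthy Versus Misinformation Health Content in Short
    Social-Media Texts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for binary classification of short health-related
    social-media posts into trustworthy information versus misinformation.
    Provides corpus ingestion and label harmonization across heterogeneous
    fact-checking datasets, tweet-style text cleaning, word-embedding
    matrices for paragraph-level two-dimensional convolution,
    cosine-similarity augmentation of the minority class with
    precision-calibrated thresholding, a four-pathway 2-D convolutional
    text classifier, classic and recurrent comparison models, stratified
    cross-validation with ROC analysis, and a synthetic tweet-corpus
    generator so the whole pipeline runs without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    e1071,
    jsonlite,
    randomForest,
    rpart,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
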