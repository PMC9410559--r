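Package: pirnarank
Title: Learning-to-Rank Prediction of piRNA-Disease Associations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Ranks candidate diseases for query piRNAs with a stacked
    learning-to-rank pipeline. Association features are built from
    normalized Smith-Waterman sequence similarities and Wang-style
    disease-ontology semantic similarities; four component scorers
    (neighbourhood collaborative filtering, ridge logistic regression,
    random forest, linear support vector machine) are stacked and a
    LambdaMART listwise ranker is trained on their scores to optimize
    NDCG at a truncation level. Supports both the missing-association
    scenario (known piRNAs) and the cold-start scenario (newly detected
    piRNAs), with grouped retrieval metrics (NDCG@k, MAP, truncated ROC,
    AUC, AUPR), five-fold cross-validation, coordinate-wise
    hyperparameter search, and a synthetic benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    randomForest,
    e1071,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
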