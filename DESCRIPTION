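Package: adrenomir
Title: miRNA Panel Classification of Adrenocortical Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for discriminating adrenocortical
    carcinoma (ACC) from adenoma (ACA) using tissue miRNA RT-qPCR panels:
    delta-Ct normalization against combined intrinsic (RNU48) and spike-in
    (cel-miR-39) controls, random-forest importance ranking, exhaustive
    2-4 miRNA combination search scored by repeated stratified 90-10
    learner-tester neural-network cross-validation, per-sample majority-vote
    ensemble classification of unknown samples, and diagnostic evaluation
    (sensitivity, specificity, PPV, NPV, ROC/AUC). Includes a synthetic
    Ct-table generator reproducing the study design (triplicate wells,
    censored low-expression measurements, discovery and validation cohorts)
    so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    randomForest,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
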