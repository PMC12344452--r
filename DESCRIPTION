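Package: tailkin
Title: Tail Kinematics Analysis for Detection-Dog Search Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing tail-wagging kinematics of detection dogs
    searching a scent wall, starting from markerless pose-tracking output.
    Reads per-frame body-landmark tables and behavioural event logs, splits
    trials into per-area search segments with alert-window excision, computes
    body-centred tail angle, angular velocity and per-segment lateralization
    features, and classifies target versus non-target search segments with a
    gated recurrent unit sequence model and a gradient-boosting plus
    support-vector ensemble under leave-one-dog-out and k-fold protocols.
    Includes landmark-detector evaluation metrics (RMSE, PCK), ROC/AUC
    comparison via the DeLong test, dog-stratified permutation tests for
    area effects, expert-survey analytics, and a synthetic trajectory
    generator that emulates overhead 60 fps recordings of individually
    parameterized wagging dogs so the full pipeline is testable without
    video data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    e1071,
    xgboost,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
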