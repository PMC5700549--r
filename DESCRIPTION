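Package: stressbn
Title: Discrete Bayesian Networks for Occupational Stress in Working-Conditions Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to model occupational stress from working-conditions survey
    data with discrete Bayesian networks, in the Demands-Control-Social
    Support-Recognition tradition. The package recodes raw European Working
    Conditions Survey (EWCS) question codes into ten categorical study
    variables, learns a network by score-based hill climbing (BIC or BDeu),
    estimates conditional probability tables, answers exact posterior queries
    by variable elimination, tabulates scenario sensitivity analyses of the
    stress posterior under evidence grids, and evaluates the network as a
    stress classifier with k-fold cross-validated ROC/AUC. A calibrated
    synthetic-data generator reproducing the published marginal frequencies of
    the 2,211-record healthcare subset of the 6th EWCS makes every pipeline
    stage testable without access to the restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
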