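Package: fairdep
Title: Fairness Auditing and Bias Mitigation for Clinical Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing group fairness of binary clinical risk
    prediction models on tabular cohort data and for mitigating the biases
    found. Implements subgroup true/false-positive rates, the Equal
    Opportunity Difference (EOD) and Average Odds Difference (AOD) fairness
    metrics, balanced accuracy, AUC-ROC, and a weighted harmonic
    fairness-accuracy score; five bias-mitigation techniques spanning
    pre-processing (attribute suppression, sample reweighing, disparate
    impact removal by quantile repair) and post-processing (calibrated
    equalized-odds score mixing, and population sensitivity-guided
    per-group threshold adjustment); a stratified cross-validated scenario
    runner comparing base and mitigated classifiers; and a synthetic cohort
    generator with group-dependent outcome prevalence and proxy features
    for end-to-end testing without access to restricted cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
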