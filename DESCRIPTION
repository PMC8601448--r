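Package: tcpthick
Title: Modeling Top Cognitive Performance from Regional Cortical Thickness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for asking whether regional cortical
    thickness can model Top Cognitive Performance (TCP) in healthy elderly
    cohorts. Provides percentile-based TCP labeling from delayed-recall and
    Trails-B scores, maximum-likelihood logistic models of TCP status on
    Desikan-Killiany-Tourville (DKT) cortical ROI thickness (an a priori
    six-region cingulate model and forward selection over all 62 regions),
    ROC/AUC evaluation with a label-permutation null that rebuilds the model
    per shuffle, a DeLong contrast for correlated AUCs, stratified-bootstrap
    region-selection-frequency analysis with a shuffled-label chance
    baseline and a selection-profile shape classifier, demographic group
    comparisons, and a synthetic cohort generator with planted thickness
    effects so the full pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
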