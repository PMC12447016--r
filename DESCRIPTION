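Package: panelagree
Title: Agreement and Diagnostic Accuracy of Classifiers Against Listening Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating an automated lung-sound classifier against a
    physician listening panel: staged consensus adjudication of panel
    annotations, interpretability gating, patient-level aggregation of chest
    position labels, majority-vote ensembling of classifier iterations,
    chance-adjusted agreement statistics (Cohen's kappa and Brennan-Prediger),
    diagnostic accuracy metrics with exact and log-scale confidence intervals,
    design-effect sample size for clustered agreement proportions, and a
    seeded synthetic annotation generator for end-to-end verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
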