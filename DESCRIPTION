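Package: robrank
Title: Text-Mining Assistance for Risk-of-Bias Assessments in Systematic Reviews
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ranks sentences of clinical-trial reports by relevance to the
    risk-of-bias properties sequence generation, allocation concealment and
    blinding, ranks articles by predicted risk of bias, and triages articles
    to single-reviewer assessment. Labels are inferred from Cochrane-style
    assessment records (supporting quotations and "no information"
    statements), features are stemmed bag-of-words counts, models are
    unregularized logistic regressions fitted by stochastic gradient
    descent, and triage thresholds are derived from published
    inter-reviewer disagreement rates. Includes a seed-reproducible
    synthetic corpus generator so the full pipeline is testable without
    access to the original assessment data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
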