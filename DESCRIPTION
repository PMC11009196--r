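Package: frailtymark
Title: Frailty-Index Versus Single-Biomarker Mortality Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the prognostic accuracy of individual
    frailty biomarkers against deficit-accumulation frailty indices for a
    binary mortality outcome. Provides dictionary-driven deficit coding
    (binary normal-range, ordinal cut-point, and min-max normalized rules),
    frailty-index construction with the 80 percent completeness rule and
    leave-one-out variants, nested weighted logistic mortality models,
    weighted AUC estimation with a DeLong-type equality test for correlated
    ROC curves, Benjamini-Hochberg screening at a fixed false discovery
    rate, and a seeded synthetic-cohort generator calibrated to published
    population marginals so the full pipeline can be exercised without
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
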