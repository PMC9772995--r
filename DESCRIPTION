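Package: padxplain
Title: Explainable Prediction of Country-Level Dementia Prevalence from
    Lifestyle Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A per-year pipeline that predicts age-standardized dementia
    prevalence (PAD, per 100,000) across countries from panels of intensive
    lifestyle indicators, and explains the predictions. Stages: two-rule gap
    filling (quadratic-in-year interpolation or series mean), per-year
    standardization, shadow-feature (Boruta-style) selection around a random
    forest, a feature competition network with Shannon-entropy edge weights,
    repeated k-fold cross-validated random-forest regression with permutation
    p-values, and per-country Shapley attribution with a 25-percent-of-total
    retention rule. Includes a synthetic panel generator with known ground
    truth so selection, regression and attribution are verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ranger,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
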