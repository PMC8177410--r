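Package: lripu
Title: Hybrid Logistic Regression with Evolutionary Product-Unit Networks
    for Lung Transplant Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling six-month lung-graft survival from encoded
    donor-recipient covariates. Implements product-unit neural networks
    (multiplicative basis functions with real exponents), a mutation-only
    evolutionary algorithm that searches their architecture and weights
    (EPUNN), and the hybrid classifier that combines the original covariates
    with the evolved product units in a ridge-stabilised logistic regression
    (LRIPU). Includes the 36-covariate donor-recipient encoding schema,
    design scaling to the [1, 2] range, a synthetic cohort generator with
    known ground truth, a parser and interpreter for printed model
    expressions, classification metrics, and a donor-recipient ranking
    utility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
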