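Package: oradsped
Title: O-RADS MRI Classification and Validation Statistics for Pediatric Adnexal Masses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A deterministic rule engine for the Ovarian-Adnexal Reporting and
    Data System (O-RADS) MRI classification of pediatric adnexal lesions from
    structured imaging descriptors, together with a simplified two-level
    (likely benign / likely malignant) reading framework, validation
    statistics (binomial proportion confidence intervals by the Wilson score
    and Clopper-Pearson methods, linearly weighted Cohen's kappa, Firth
    penalized logistic regression for predictor screening, median/IQR
    summaries), and a synthetic cohort module: a canonical 109-patient
    fixture that reproduces the published validation study's marginal counts
    exactly, plus a seeded stochastic generator with the same statistical
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
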