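Package: agreelog
Title: Log-Linear Agreement Models for Multi-Rater Diagnostic Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Evaluates a computer-aided diagnosis system against multiple
    expert readers when no gold standard exists, using log-linear models
    for the K-way contingency table of categorical readings.  Provides a
    nested ladder of agreement models (independence, homogeneous and
    category-specific diagonal agreement, pairwise and three-way agreement
    terms) fitted by Poisson maximum likelihood, likelihood-ratio model
    selection, Wald tests of linear hypotheses on agreement strengths
    (including expert-equivalence tests for a CAD reader), classical
    comparator statistics (per-category percent agreement, Cohen's and
    weighted kappa), and a multinomial simulator for power and
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), e1071, optparse
Config/testthat/edition: 3
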