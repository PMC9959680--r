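Package: pyrroqsar
Title: Low-Data QSAR Workflow for Pyrrole Antioxidant Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative structure-activity relationship (QSAR) modelling
    toolkit for small congeneric series of pyrrole antioxidants. Implements
    Kennard-Stone representative train/test splitting, genetic-algorithm
    (GFA-style) descriptor-subset selection scored by multiple linear
    regression, a full regression-diagnostics suite (R2, significance-of-
    regression F, leave-one-out PRESS and cross-validated R2, RMSE, Pearson
    correlation screening), a 3-3-1 multilayer perceptron trained by
    Levenberg-Marquardt with Bayesian regularization, and activity-threshold
    screening of newly designed compounds. Includes a seeded synthetic-data
    generator that emulates quantum-chemical descriptor tables and planted
    linear or nonlinear activity models for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
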