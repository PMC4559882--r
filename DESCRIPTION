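Package: qpcrBayes
Title: Bayesian Two-Class Classification from qRT-PCR Triplicate Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds, validates and applies a Gaussian Bayes two-class
    classifier from small-panel qRT-PCR cycle-threshold triplicates.
    Provides replicate-variance quality control with chi-square(2)
    variance-law fitting by Kolmogorov-Smirnov minimisation and
    outlier rejection, reference-gene (delta-Ct) normalisation with a
    cross-session accuracy audit, per-class Gaussian modelling with
    normality screening and Welch separation tests, an optimal
    quadratic decision threshold with propagated uncertainty,
    posterior-odds reliability bands, bias-outlier detection, and
    correlation-based noise reduction of the discriminating measure.
    Includes a synthetic-cohort generator reproducing the statistical
    structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
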