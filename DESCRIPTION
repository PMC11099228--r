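Package: axismr
Title: Two-Sample Mendelian Randomization Mediation Analysis Along the Gut-Lung Axis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) with summary
    statistics, oriented at mediation questions of the form exposure ->
    mediator -> outcome (gut microbiota -> immune cell -> lung cancer).
    Implements instrumental-variable selection (p-value thresholding, greedy
    LD clumping against a user-supplied r-squared matrix, outcome-association
    exclusion, palindromic-SNP removal, F-statistic and minor-allele-frequency
    filters), allele harmonization, five univariable MR estimators (Wald
    ratio, inverse-variance weighted, MR-Egger, weighted median, mode-based),
    multivariable IVW, a four-step mediator screen with product-of-coefficients
    mediation quantification, a sensitivity suite (Cochran's Q, Egger
    intercept, MR-PRESSO global/outlier/distortion tests, leave-one-out), and
    a seeded synthetic summary-statistics generator with known causal truth
    for end-to-end validation.
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
    withr
Config/testthat/edition: 3
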