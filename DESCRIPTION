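Package: mrmediate
Title: Two-Sample Mendelian Randomization Screening and Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) screens of
    GWAS summary statistics and for two-step / multivariable MR mediation
    analysis. Covers instrument selection (p-value screening, greedy LD
    clumping, palindromic-variant exclusion, per-SNP explained variance and
    F-statistics), cross-dataset harmonization of effect alleles, five
    univariable causal estimators (inverse-variance weighted with a
    multiplicative random-effects fallback, MR-Egger, weighted median,
    weighted mode, simple mode), heterogeneity and pleiotropy diagnostics
    (Cochran's Q, MR-PRESSO global/outlier/distortion tests, leave-one-out),
    Benjamini-Hochberg tiering of screen results, multivariable MR direct
    effects, and the product-of-coefficients mediation calculus with
    delta-method standard errors. A seeded generator of multi-trait GWAS
    summary statistics under a known exposure-mediator-outcome structural
    model supports fully offline testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
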