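Package: dftwin
Title: DeFries-Fulker Regression Analysis of Twin Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Variance decomposition of outcomes measured on monozygotic and
    dizygotic twin pairs using DeFries-Fulker (DF) kinship regression.
    Implements double entry of twin pairs, co-twin mean-centering, the
    classic and revised DF equations, specific nonshared-environment
    difference-score (ENVDIF) predictors, and Huber-White cluster-robust
    standard errors over pairs.  Includes a seeded ACE twin-data simulator
    with ground-truth recording, constructors for adolescent nutrition and
    physical-activity survey measures, a Tables-style model suite, and a
    Monte Carlo parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
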