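Package: mlgrm
Title: Multilevel Graded Response Models for Nested Ordinal Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step multilevel item response theory (MLIRT) analysis for
    ordinal health-survey data with persons nested in dwellings. A graded
    response measurement model is coupled to a two-level structural regression
    of the latent trait on person- and dwelling-level covariates with dwelling
    random effects, estimated by Markov chain Monte Carlo with data
    augmentation and per-iteration identification rescaling. Includes the
    standard item response theory assumption diagnostics (bifactor
    unidimensionality, residual-correlation local dependence, rest-score
    monotonicity), polychoric correlations, highest posterior density
    summaries, the deviance information criterion, and a synthetic generator
    for nested ordinal survey data with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    truncnorm,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    optparse,
    withr
Config/testthat/edition: 3
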