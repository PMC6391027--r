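Package: dualfactor
Title: Ordinal Confirmatory Factor Models for Mental-Health Difficulties and Wellbeing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Confirmatory factor analysis for mixed ordinal and continuous
    mental-health item batteries: polychoric, polyserial and Pearson
    correlation estimation with asymptotic covariance, diagonally weighted
    least squares (WLSMV-style) model fitting with a mean-and-variance
    adjusted test statistic, correlated-factors, classical bifactor and S-1
    bifactor structures, explained-common-variance and
    percent-uncontaminated-correlations dimensionality indices, categorical
    multigroup measurement-invariance testing, latent regression on binary
    covariates, and a synthetic-data generator emulating a two-instrument
    early-adolescent survey design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
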