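Package: standgrowth
Title: Stand Growth-Curve Modelling with Environmental Covariates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits and compares the classical diameter-height and age-diameter
    growth-curve forms used in forest inventory analysis (linear, logarithmic,
    reciprocal, quadratic, cubic, S-curve, growth and logistic), extends the
    selected form with screened environmental covariates (elevation,
    precipitation, temperature extremes), validates on a random hold-out
    partition with mean error, mean relative error, root mean squared error
    and R-squared, and benchmarks against a small tanh feedforward neural
    network trained by Levenberg-Marquardt with weight decay and early
    stopping. Includes a seeded stand-inventory simulator with species
    profiles (truncated-normal age structure, growth-curve responses,
    Gaussian-copula covariates) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
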