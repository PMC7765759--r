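Package: lcens
Title: Summary Statistics for Left-Censored Lognormal Concentration Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the geometric mean, geometric standard deviation,
    arithmetic mean and standard deviation, and 95% intervals for the mean
    of univariate concentration data containing nondetects (left-censored
    observations), under a lognormal model. Implements six estimators:
    discarding nondetects, substitution of half the reporting limit, the
    Kaplan-Meier product-limit estimator applied through the flip
    transform, robust regression on order statistics with
    Hirsch-Stedinger plotting positions, censored maximum likelihood, and
    a Bayesian censored model sampled by Markov chain Monte Carlo in
    which the unknown reporting limit is itself a parameter. Interval
    estimation covers Cox's method, the bias-corrected and accelerated
    (BCa) bootstrap, and equal-tailed credible intervals; the Bayesian
    fit additionally provides posterior-predictive simulation and WAIC.
    A simulation engine benchmarks the estimators by bias, mean squared
    error, coverage probability, and the relative spread (RSD, RIQR) of
    their sampling distributions across censoring fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
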