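# lcens

Summary statistics for left-censored lognormal concentration data.

Trace-level chemical surveys — contaminants in food, drinking water or
environmental media — routinely report a large share of their measurements
only as "below the reporting limit" (nondetects). With half or more of the
data censored this way, the common habits of discarding nondetects or
substituting half the reporting limit (RL) badly distort the mean, the
geometric mean (GM) and especially the geometric standard deviation (GSD)
of the underlying concentration distribution.

`lcens` estimates GM, GSD, arithmetic mean/SD and a 95% interval for the
mean of a lognormal concentration distribution from a univariate sample
with nondetects, by six methods:

| method | idea | interval |
|--------|------|----------|
| `dn`   | discard nondetects | Cox's method |
| `rl2`  | substitute RL/2 for nondetects | Cox's method |
| `km`   | Kaplan–Meier product-limit CDF via the flip transform | BCa bootstrap |
| `ros`  | robust regression on order statistics (Hirsch–Stedinger positions) | BCa bootstrap |
| `mle`  | censored maximum likelihood: detects enter the density, nondetects the CDF at the RL | BCa bootstrap |
| `mcmc` | Bayesian censored model with the RL itself a parameter on (0, min detect], sampled by adaptive MCMC | credible interval |

For the Bayesian fit the likelihood is

    L(m, s, rl) = prod_{x in detects} f(x | m, s) * F(rl | m, s)^c

with `f`/`F` the lognormal density/CDF, `c` the nondetect count, and
`rl <= min(detects)`; point estimates are expected-a-posteriori (EAP)
means of the per-draw GM = `exp(m)`, GSD = `exp(s)`, mean and SD. The
package also provides posterior-predictive simulation, WAIC, and a
simulation engine (`run_study()`) that benchmarks all six methods by bias,
MSE, coverage probability, RSD and RIQR across censoring fractions — see
the methods vignette (`vignettes/censored-lognormal-estimation.Rmd`) for
the model, priors, and design decisions.

## Worked example

Simulate a 150-sample survey from a lognormal with GM = 0.082e-3 mg/L and
GSD = 4.9, censor below the theoretical 57th percentile (the kind of
censoring fraction real trace-contaminant surveys show), and fit:

```r
library(lcens)
truth <- lnorm_params(gm = 0.082e-3, gsd = 4.9)
x     <- generate_dataset(truth, 150, seed = 20)
water <- apply_censoring(x, truth, 0.57)
water
#> Left-censored sample: n = 150 (63 detected, 87 censored)
#> Reporting limit: 0.0001106479

fit <- cenfit(water, method = "mcmc", seed = 42)
summary(fit)
#> Left-censored lognormal fit (MCMC)
#> n = 150 (87 censored, RL = 0.0001106)
#>   GM = 7.977e-05  GSD = 5.35
#>   mean = 0.0003273  SD = 0.001461
#>   95% credible interval for the mean: [0.0002155, 0.000559]
#> convergence (split R-hat): meanlog 1.021, sdlog 1.019, rl 1.015
#> EAP reporting limit: 0.0001077
```

The EAP geometric mean (7.98e-05) and GSD (5.35) recover the generating
values (8.2e-05 and 4.9) despite 58% censoring, and the credible interval
for the mean covers the true mean 2.89e-04. Comparing all six methods on
the same sample:

```r
estimate_table(water, methods = c("dn", "rl2", "km", "ros", "mle", "mcmc"),
               seed = 42)
#>  method     mean       sd      lci      uci       gm  gsd
#>      DN 0.000526 0.000498 0.000414 0.000656 3.76e-04 2.25
#>    RL/2 0.000253 0.000397 0.000179 0.000276 1.24e-04 2.95
#>      KM 0.000285 0.000382 0.000237 0.000361 1.85e-04 2.22
#>     ROS 0.000250 0.000400 0.000195 0.000328 9.62e-05 4.26
#>     MLE 0.000289 0.000954 0.000217 0.000423 8.40e-05 4.82
#>    MCMC 0.000327 0.001461 0.000216 0.000559 7.98e-05 5.35
```

Discarding nondetects (DN) inflates the mean by ~80% and halves the GSD;
substitution (RL/2) and KM understate the spread; the likelihood-based
fits (MLE, MCMC) recover the heavy tail. `run_study()` turns this
one-sample impression into a replicated benchmark:

```r
design <- study_design(censoring = seq(0.1, 0.9, 0.1), replicates = 1000,
                       methods = c("dn", "rl2", "km", "ros", "mle"),
                       intervals = FALSE, seed = 1)
report <- run_study(design)
plot(report, criterion = "bias", quantity = "gsd")
```

A command-line interface over the same functions ships in
`inst/cli/lcens.R` (subcommands `estimate`, `simulate`, `posterior`,
`version`).

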