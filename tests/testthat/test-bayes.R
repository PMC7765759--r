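flat <- function() prior_spec(meanlog_mean = 0, meanlog_sd = Inf,
                              sdlog_scale = Inf)

test_that("log_posterior matches term-by-term summation and the flat limit", {
  s <- toy_a()
  det <- s$values[!s$censored]
  got <- log_posterior(0, 1, 0.2, s, priors = flat())
  expect_equal(got, oracle_cens_loglik(0, 1, 0.2, det, 5), tolerance = 1e-12)
  # no censoring + flat priors = plain uncensored log-likelihood
  su <- censored_sample(det)
  expect_equal(log_posterior(0.3, 0.8, 0.1, su, priors = flat()),
               sum(dlnorm(det, 0.3, 0.8, log = TRUE)), tolerance = 1e-12)
  # informative priors add the prior log densities (half-normal at default)
  pri <- prior_spec(meanlog_mean = -1, meanlog_sd = 2, sdlog_scale = 1.5)
  expect_equal(log_posterior(0, 1, 0.2, s, priors = pri),
               oracle_cens_loglik(0, 1, 0.2, det, 5) +
                 dnorm(0, -1, 2, log = TRUE) +
                 dnorm(1, 0, 1.5, log = TRUE) + log(2),
               tolerance = 1e-12)
})

test_that("log_posterior respects the support and is monotone in rl", {
  s <- toy_a()
  expect_identical(log_posterior(0, -1, 0.1, s, flat()), -Inf)
  expect_identical(log_posterior(0, 1, 0, s, flat()), -Inf)
  expect_identical(log_posterior(0, 1, 0.21, s, flat()), -Inf) # above min detect
  rls <- seq(0.01, 0.2, length.out = 20)
  lp <- vapply(rls, function(r) log_posterior(0, 1, r, s, flat()), numeric(1))
  expect_true(all(diff(lp) > 0)) # censored CDF term grows with rl
})

test_that("the sampler is deterministic given a seed and keeps its bookkeeping", {
  s <- make_censored_sample(50, 1, 3, 0.4, seed = 41)
  cfg <- mcmc_config(chains = 2, iterations = 800, warmup = 400, thin = 2,
                     seed = 5)
  d1 <- suppressWarnings(sample_posterior(s, config = cfg))
  d2 <- suppressWarnings(sample_posterior(s, config = cfg))
  expect_equal(as.data.frame(d1), as.data.frame(d2))
  expect_equal(nrow(d1), 2 * (800 - 400) / 2)
  expect_true(all(d1$sdlog > 0))
  expect_true(all(d1$rl > 0 & d1$rl <= min(s$values[!s$censored])))
  # per-draw derived quantities satisfy the lognormal identities
  expect_equal(d1$gm, exp(d1$meanlog), tolerance = 1e-12)
  expect_equal(d1$mean, d1$gm * exp(log(d1$gsd)^2 / 2), tolerance = 1e-12)
})

test_that("with ample uncensored data the posterior matches the MLE", {
  x <- generate_dataset(lnorm_params(gm = 1, gsd = 3), 500, seed = 42)
  s <- censored_sample(x)
  d <- suppressWarnings(sample_posterior(s, config = mcmc_config(seed = 6)))
  ml <- mean(log(x))
  sl <- sqrt(mean((log(x) - ml)^2))
  expect_lt(abs(eap(d, "meanlog") - ml), 3 * sd(d$meanlog))
  expect_lt(abs(eap(d, "sdlog") - sl), 3 * sd(d$sdlog))
})

test_that("credible intervals for GM and GSD are calibrated under censoring", {
  # scaled-down parameter-recovery check at 50% censoring
  p <- lnorm_params(gm = 0.082e-3, gsd = 4.9)
  pri <- prior_spec(meanlog_mean = log(0.082e-3), meanlog_sd = 1,
                    sdlog_mean = log(4.9), sdlog_scale = 0.5)
  hits <- vapply(1:40, function(r) {
    s <- make_censored_sample(150, 0.082e-3, 4.9, 0.5, seed = 500 + r)
    d <- suppressWarnings(sample_posterior(
      s, pri, mcmc_config(2, 1000, 500, 1, seed = r)))
    gm_ci <- credible_interval(d, "gm")
    gsd_ci <- credible_interval(d, "gsd")
    c(gm_ci[["lci"]] <= 0.082e-3 && 0.082e-3 <= gm_ci[["uci"]],
      gsd_ci[["lci"]] <= 4.9 && 4.9 <= gsd_ci[["uci"]])
  }, logical(2))
  # 95% nominal; 3 binomial SEs at 40 replicates is about 0.10
  expect_gte(mean(hits[1, ]), 0.85)
  expect_gte(mean(hits[2, ]), 0.85)
})

test_that("EAP is the draw mean and handles the Jensen gap correctly", {
  d <- fake_draws(meanlog = log(c(1, 2, 3)), sdlog = c(0.5, 0.7, 0.9))
  expect_equal(eap(d, "gm"), 2)
  expect_equal(eap(d, "mean"),
               mean(exp(log(c(1, 2, 3))) * exp(c(0.5, 0.7, 0.9)^2 / 2)),
               tolerance = 1e-12)
  expect_error(eap(d, "nope"), class = "lcens_domain_error")
  d1 <- fake_draws(meanlog = rep(log(7), 5), sdlog = rep(0.3, 5))
  expect_equal(eap(d1, "gm"), 7)
})

test_that("credible intervals follow the median-unbiased quantile rule", {
  d <- fake_draws(meanlog = log(1:100), sdlog = rep(0.1, 100))
  ci <- credible_interval(d, "gm", 0.95)
  expect_equal(unname(ci),
               unname(quantile(1:100, c(0.025, 0.975), type = 8)))
  wide <- credible_interval(d, "gm", 0.999)
  expect_lt(wide[["lci"]], 2)
  expect_gt(wide[["uci"]], 99)
  dc <- fake_draws(meanlog = rep(0, 120), sdlog = rep(0.2, 120))
  expect_equal(diff(unname(credible_interval(dc, "gm"))), 0)
  expect_error(credible_interval(fake_draws(log(1:50), rep(0.1, 50)), "gm"),
               class = "lcens_insufficient_draws")
})

test_that("posterior predictive has the contracted size and mean", {
  s <- make_censored_sample(80, 1, 3, 0.3, seed = 43)
  d <- suppressWarnings(sample_posterior(s, config = mcmc_config(seed = 7)))
  pp <- posterior_predictive(d, seed = 8)
  expect_length(pp, nrow(d) * 50)
  # law of total expectation: predictive mean ~ EAP of the mean
  se <- sd(pp) / sqrt(length(pp))
  expect_lt(abs(mean(pp) - eap(d, "mean")), 3 * se + 0.02 * eap(d, "mean"))
  # degenerate draw
  d0 <- fake_draws(meanlog = log(4), sdlog = 0)
  expect_true(all(posterior_predictive(d0, per_draw = 10, seed = 1) == 4))
})

test_that("WAIC matches direct summation and is additive over observations", {
  s <- toy_a()
  d <- fake_draws(meanlog = seq(-0.5, 0.4, 0.1), sdlog = seq(0.8, 1.7, 0.1),
                  rl = rep(0.2, 10))
  got <- waic(d, s)
  det <- s$values[!s$censored]
  ll <- cbind(sapply(det, function(x) dlnorm(x, d$meanlog, d$sdlog, log = TRUE)),
              matrix(rep(plnorm(d$rl, d$meanlog, d$sdlog, log.p = TRUE), 5),
                     nrow = 10))
  lppd <- sum(log(colMeans(exp(ll - max(ll)))) + max(ll))
  p_waic <- sum(apply(ll, 2, var))
  expect_equal(got[["lppd"]], lppd, tolerance = 1e-10)
  expect_equal(got[["p_waic"]], p_waic, tolerance = 1e-10)
  expect_equal(got[["waic"]], -2 * (lppd - p_waic), tolerance = 1e-10)
  # identical draws: p_waic = 0 and waic = -2 * total log likelihood
  d1 <- fake_draws(meanlog = rep(0, 5), sdlog = rep(1, 5), rl = rep(0.2, 5))
  got1 <- waic(d1, s)
  expect_equal(got1[["p_waic"]], 0, tolerance = 1e-12)
  expect_equal(got1[["waic"]], -2 * oracle_cens_loglik(0, 1, 0.2, det, 5),
               tolerance = 1e-10)
  # duplicating an observation adds exactly its pointwise contribution
  s2 <- censored_sample(c(s$values, 1), c(s$censored, FALSE))
  extra <- log(mean(dlnorm(1, d$meanlog, d$sdlog)))
  expect_equal(waic(d, s2)[["lppd"]], got[["lppd"]] + extra, tolerance = 1e-10)
})

test_that("MCMC schedule validation and convergence gates work", {
  expect_error(mcmc_config(warmup = 2000, iterations = 2000),
               class = "lcens_invalid_parameter")
  expect_error(mcmc_config(iterations = 1001, warmup = 500, thin = 2),
               class = "lcens_invalid_parameter")
  cfg <- mcmc_config()
  expect_equal(cfg$chains * (cfg$iterations - cfg$warmup) / cfg$thin, 2000)
})
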