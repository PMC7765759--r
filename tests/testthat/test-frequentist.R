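fit_est <- function(sample, method, ...) {
  cenfit(sample, method = method, interval = "none", ...)$estimates
}

test_that("DN computes statistics from detects only", {
  e <- fit_est(toy_a(), "dn")
  expect_equal(e[["mean"]], 1.74) # (0.2+0.5+1+2+5)/5
  expect_equal(e[["gm"]], 1) # product of detects is 1, fifth root 1
  expect_equal(e[["sd"]], sd(c(0.2, 0.5, 1, 2, 5)))
  expect_equal(e[["gsd"]], exp(sd(log(c(0.2, 0.5, 1, 2, 5)))))
})

test_that("with no censoring DN, RL/2, KM and ROS reduce to plain statistics", {
  x <- generate_dataset(lnorm_params(gm = 1, gsd = 2.5), 40, seed = 3)
  s <- censored_sample(x)
  ref <- fit_est(s, "dn")
  for (m in c("rl2", "km", "ros"))
    expect_equal(fit_est(s, m), ref, tolerance = 1e-12, label = m)
  # MLE differs only through the n vs n-1 denominator of sdlog
  e <- fit_est(s, "mle")
  expect_equal(e[["gm"]], ref[["gm"]], tolerance = 1e-5)
  expect_equal(log(e[["gsd"]]),
               sd(log(x)) * sqrt((length(x) - 1) / length(x)),
               tolerance = 1e-5)
})

test_that("substitution replaces nondetects by fraction * RL", {
  e <- fit_est(toy_a(), "rl2")
  expect_equal(e[["mean"]], (8.7 + 5 * 0.1) / 10) # 0.92
  e1 <- fit_est(toy_a(), "rl2", sub_fraction = 1)
  expect_equal(e1[["mean"]], (8.7 + 5 * 0.2) / 10)
  s_norl <- censored_sample(c(1, 2, NA), censored = c(FALSE, FALSE, TRUE),
                            rl = NA)
  expect_error(cenfit(s_norl, method = "rl2", interval = "none"),
               class = "lcens_missing_rl")
  expect_error(cenfit(toy_a(), method = "rl2", interval = "none",
                      sub_fraction = 0), class = "lcens_invalid_parameter")
})

test_that("estimators demand enough detects", {
  s1 <- censored_sample(c(5, NA, NA), censored = c(FALSE, TRUE, TRUE))
  expect_error(cenfit(s1, method = "dn", interval = "none"),
               class = "lcens_insufficient_data")
  s2 <- censored_sample(c(5, 7, NA), censored = c(FALSE, FALSE, TRUE))
  expect_error(cenfit(s2, method = "ros", interval = "none"),
               class = "lcens_insufficient_data")
})

test_that("KM matches the product-limit oracle on flipped data", {
  skip_if_not_installed("survival")
  for (s in list(toy_a(),
                 make_censored_sample(60, 1, 3, 0.35, seed = 21),
                 make_censored_sample(45, 0.082e-3, 4.9, 0.6, seed = 22))) {
    got <- cenfit(s, method = "km", interval = "none")$meta$cdf
    want <- oracle_km_cdf(s)
    expect_equal(got$x, want$x, tolerance = 1e-12)
    expect_equal(got$w, want$w, tolerance = 1e-12)
  }
  # hand-enumerated mean for the toy sample: each detect carries 1/10,
  # the censored tail mass 5/10 sits at the smallest detect 0.2
  e <- fit_est(toy_a(), "km")
  expect_equal(e[["mean"]], 0.6 * 0.2 + 0.1 * (0.5 + 1 + 2 + 5))
})

test_that("KM mean is bounded by zero- and RL-substitution", {
  s <- make_censored_sample(80, 1, 3, 0.4, seed = 23)
  km <- fit_est(s, "km")[["mean"]]
  det <- s$values[!s$censored]
  lo <- sum(det) / s$n
  hi <- (sum(det) + sum(s$censored) * s$rl) / s$n
  expect_gte(km, lo)
  expect_lte(km, hi + 1e-12)
})

test_that("KM flags censoring above 50%", {
  s <- censored_sample(c(1, 2, 4, 8, rep(NA, 6)),
                       censored = rep(c(FALSE, TRUE), c(4, 6)))
  expect_true(cenfit(s, method = "km", interval = "none")$meta$high_censoring)
  expect_false(cenfit(toy_a(), method = "km",
                      interval = "none")$meta$high_censoring)
})

test_that("ROS plotting positions match the exceedance-recursion oracle", {
  for (s in list(toy_a(), make_censored_sample(50, 1, 3, 0.3, seed = 24))) {
    fit <- cenfit(s, method = "ros", interval = "none")
    pp <- fit$meta$ros$plotting_positions
    want <- oracle_hs_positions(sum(!s$censored), sum(s$censored))
    expect_equal(pp$detect, want$detect, tolerance = 1e-12)
    expect_equal(pp$censored, want$censored, tolerance = 1e-12)
    expect_true(all(pp$detect > 0 & pp$detect < 1))
    expect_true(all(diff(pp$detect) >= 0))
  }
})

test_that("ROS imputations live in the censored region and preserve order", {
  s <- make_censored_sample(100, 1, 3, 0.4, seed = 25)
  ros <- cenfit(s, method = "ros", interval = "none")$meta$ros
  expect_true(all(ros$imputed_values > 0))
  expect_true(all(ros$imputed_values < s$rl))
  expect_true(all(diff(ros$imputed_values) >= 0)) # sorted with positions
  expect_length(ros$combined, s$n)
})

test_that("ROS is consistent in large samples", {
  s <- make_censored_sample(1e4, 1, 3, 0.3, seed = 9)
  e <- fit_est(s, "ros")
  expect_equal(e[["gm"]], 1, tolerance = 0.02)
  expect_equal(e[["gsd"]], 3, tolerance = 0.02)
})

test_that("uncensored MLE has the closed form with the n denominator", {
  x <- generate_dataset(lnorm_params(gm = 2, gsd = 2), 30, seed = 26)
  f <- cenfit(censored_sample(x), method = "mle", interval = "none")
  lx <- log(x)
  expect_equal(f$params$meanlog, mean(lx), tolerance = 1e-6)
  expect_equal(f$params$sdlog, sqrt(mean((lx - mean(lx))^2)), tolerance = 1e-6)
})

test_that("censored MLE maximizes the likelihood (grid-search oracle)", {
  s <- toy_a()
  det <- s$values[!s$censored]
  ll <- function(m, sg) oracle_cens_loglik(m, sg, s$rl, det, 5)
  # two-stage brute force refined to a 1e-4 grid step
  ms <- seq(-3, 2, by = 0.02)
  ss <- seq(0.1, 4, by = 0.02)
  grid <- outer(ms, ss, Vectorize(ll))
  top <- arrayInd(which.max(grid), dim(grid))
  ms <- seq(ms[top[1]] - 0.02, ms[top[1]] + 0.02, by = 1e-4)
  ss <- seq(ss[top[2]] - 0.02, ss[top[2]] + 0.02, by = 1e-4)
  grid <- outer(ms, ss, Vectorize(ll))
  top <- arrayInd(which.max(grid), dim(grid))
  f <- cenfit(s, method = "mle", interval = "none")
  expect_equal(f$params$meanlog, ms[top[1]], tolerance = 2e-4)
  expect_equal(f$params$sdlog, ss[top[2]], tolerance = 2e-4)
  # the optimum dominates the DN and substitution parameter guesses
  ll_hat <- ll(f$params$meanlog, f$params$sdlog)
  dn <- cenfit(s, method = "dn", interval = "none")$params
  rl2 <- cenfit(s, method = "rl2", interval = "none")$params
  expect_gte(ll_hat, ll(dn$meanlog, dn$sdlog))
  expect_gte(ll_hat, ll(rl2$meanlog, rl2$sdlog))
})

test_that("all estimators return gm > 0 and gsd >= 1", {
  s <- make_censored_sample(150, 0.082e-3, 4.9, 0.57, seed = 27)
  for (m in c("dn", "rl2", "km", "ros", "mle")) {
    e <- fit_est(s, m)
    expect_gt(e[["gm"]], 0)
    expect_gte(e[["gsd"]], 1)
    expect_gte(e[["sd"]], 0)
  }
})
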