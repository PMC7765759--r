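# shared fixtures and independent oracles

# 10-point toy sample: detects {0.2, 0.5, 1, 2, 5}, 5 nondetects at RL = 0.2
toy_a <- function() {
  censored_sample(c(0.2, 0.5, 1, 2, 5, rep(NA, 5)),
                  censored = rep(c(FALSE, TRUE), each = 5))
}

make_censored_sample <- function(n, gm, gsd, p, seed) {
  params <- lnorm_params(gm = gm, gsd = gsd)
  apply_censoring(generate_dataset(params, n, seed = seed), params, p)
}

# independent censored lognormal log-likelihood: direct per-observation sums
oracle_cens_loglik <- function(meanlog, sdlog, rl, det, n_cens) {
  sum(dlnorm(det, meanlog, sdlog, log = TRUE)) +
    n_cens * plnorm(rl, meanlog, sdlog, log.p = TRUE)
}

# independent Hirsch-Stedinger plotting positions, written as the literal
# two-stratum exceedance recursion (limits 0 and rl, all detects >= rl)
oracle_hs_positions <- function(n_detect, n_cens) {
  n <- n_detect + n_cens
  pe <- numeric(3) # exceedance of limits (0, rl, Inf)
  pe[3] <- 0
  A1 <- n_detect # detects in [rl, Inf)
  B1 <- n_cens # observations below rl
  pe[2] <- pe[3] + (A1 / (A1 + B1)) * (1 - pe[3])
  A0 <- 0 # detects in [0, rl)
  B0 <- 0
  pe[1] <- 1
  list(detect = (1 - pe[2]) + (pe[2] - pe[3]) * seq_len(n_detect) / (A1 + 1),
       censored = if (n_cens > 0)
         (1 - pe[2]) * seq_len(n_cens) / (B1 + 1) else numeric(0))
}

# discrete CDF of the product-limit estimate on flip-transformed data,
# computed with survival::survfit (independent of the package's closed form)
oracle_km_cdf <- function(sample) {
  vals <- sample$values
  rl <- min(vals[!sample$censored])
  vals[sample$censored] <- rl # flipped censoring time M - rl
  M <- max(vals) + 1
  fit <- survival::survfit(survival::Surv(M - vals, !sample$censored) ~ 1)
  ev <- fit$n.event > 0
  times <- fit$time[ev]
  surv <- fit$surv[ev]
  mass <- -diff(c(1, surv)) # probability mass at each flipped event time
  x <- M - times # original-scale detects, descending
  tail_mass <- surv[length(surv)] # unresolved mass below the smallest detect
  x_min <- min(x)
  mass[which.min(abs(x - x_min))] <- mass[which.min(abs(x - x_min))] + tail_mass
  o <- order(x)
  list(x = x[o], w = mass[o])
}

# naive, self-contained BCa interval for the mean under a given estimator,
# sharing the resample index matrix with the implementation under test
oracle_bca <- function(sample, indices, level, stat) {
  t0 <- stat(sample$values, sample$censored)
  tb <- apply(indices, 1, function(i)
    tryCatch(stat(sample$values[i], sample$censored[i]),
             error = function(e) NA_real_))
  tb <- tb[!is.na(tb)] # failed replicates are dropped, like the implementation
  pb <- (sum(tb < t0) + 0.5 * sum(tb == t0)) / length(tb)
  pb <- min(max(pb, 1 / (2 * length(tb))), 1 - 1 / (2 * length(tb)))
  z0 <- qnorm(pb)
  jack <- vapply(seq_len(sample$n), function(i)
    tryCatch(stat(sample$values[-i], sample$censored[-i]),
             error = function(e) NA_real_), numeric(1))
  jack <- jack[!is.na(jack)]
  dj <- mean(jack) - jack
  a <- if (sum(dj^2) > 0) sum(dj^3) / (6 * sum(dj^2)^1.5) else 0
  za <- qnorm(c((1 - level) / 2, (1 + level) / 2))
  adj <- pnorm(z0 + (z0 + za) / (1 - a * (z0 + za)))
  unname(quantile(tb, adj, type = 8))
}

# mirrors the package's root-seed -> substream derivation so tests can
# reproduce the seed a study hands to a given replicate
derive_seeds_for_test <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  out <- sample.int(.Machine$integer.max, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out
}

# posterior_draws-shaped frame with derived columns, for testing the
# draw-summary operations in isolation from the sampler
fake_draws <- function(meanlog, sdlog, rl = NULL, chains = 1) {
  n <- length(meanlog)
  if (is.null(rl)) rl <- rep(1, n)
  g2 <- sdlog^2
  df <- data.frame(chain = rep_len(seq_len(chains), n), iteration = seq_len(n),
                   meanlog = meanlog, sdlog = sdlog, rl = rl,
                   gm = exp(meanlog), gsd = exp(sdlog),
                   mean = exp(meanlog + g2 / 2))
  df$sd <- df$mean * sqrt(expm1(g2))
  structure(df, class = c("posterior_draws", "data.frame"))
}
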