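# The five non-Bayesian estimators. Each fit_* returns
# list(estimates = c(gm, gsd, mean, sd), params = lnorm_params or NULL,
#      meta = list(...)). Interval attachment lives in intervals.R / cenfit.R.

# summary statistics from a full-length positive value vector:
# arithmetic mean/SD with the n-1 denominator, GM/GSD as exp of the
# mean/SD (n-1) of the logs
plain_stats <- function(x) {
  lx <- log(x)
  s <- if (length(x) > 1) stats::sd(x) else 0
  ls <- if (length(x) > 1) stats::sd(lx) else 0
  c(gm = exp(mean(lx)), gsd = exp(ls), mean = mean(x), sd = s)
}

# -- discard nondetects (DN) -------------------------------------------------

fit_dn <- function(sample) {
  det <- detected_values(sample)
  if (length(det) < 2)
    stop_lcens("DN needs at least 2 detected values", "lcens_insufficient_data")
  est <- plain_stats(det)
  list(estimates = est,
       params = lnorm_params(meanlog = log(est[["gm"]]), sdlog = log(est[["gsd"]])),
       meta = list(n_used = length(det)))
}

# -- substitution of fraction * RL (default RL/2) ----------------------------

fit_substitution <- function(sample, fraction = 0.5) {
  if (is.na(sample$rl))
    stop_lcens("substitution needs a known reporting limit", "lcens_missing_rl")
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop_lcens("fraction must lie in (0, 1]", "lcens_invalid_parameter")
  full <- sample$values
  full[sample$censored] <- fraction * sample$rl
  est <- plain_stats(full)
  list(estimates = est,
       params = lnorm_params(meanlog = log(est[["gm"]]), sdlog = log(est[["gsd"]])),
       meta = list(substituted = fraction * sample$rl,
                   n_substituted = n_censored(sample)))
}

# -- Kaplan-Meier via the flip transform -------------------------------------

# Discrete CDF implied by the product-limit estimate of left-censored data
# under a single reporting limit at (or below) the minimum detect: flipping
# x -> M - x turns nondetects into right-censored points beyond every event,
# so each detect carries probability 1/n and the unresolved tail mass c/n
# sits below the smallest detect, where it is assigned to the smallest
# detect. (This makes the KM mean coincide with substituting the RL for
# nondetects, the known single-RL behaviour.)
km_cdf <- function(sample) {
  det <- sort(detected_values(sample))
  n <- sample$n
  w <- rep(1 / n, length(det))
  w[1] <- w[1] + n_censored(sample) / n
  list(x = det, w = w)
}

fit_km <- function(sample) {
  det <- detected_values(sample)
  if (length(det) < 1)
    stop_lcens("KM needs at least one detected value", "lcens_insufficient_data")
  cdf <- km_cdf(sample)
  n <- sample$n
  corr <- if (n > 1) n / (n - 1) else 1 # match the n-1 convention of the others
  wmean <- function(x, w) sum(w * x)
  wsd <- function(x, w) sqrt(corr * sum(w * (x - wmean(x, w))^2))
  m <- wmean(cdf$x, cdf$w)
  s <- wsd(cdf$x, cdf$w)
  lx <- log(cdf$x)
  gm <- exp(wmean(lx, cdf$w))
  gsd <- exp(wsd(lx, cdf$w))
  cens_frac <- n_censored(sample) / n
  list(estimates = c(gm = gm, gsd = gsd, mean = m, sd = s),
       params = lnorm_params(meanlog = log(gm), sdlog = log(gsd)),
       meta = list(cdf = cdf,
                   high_censoring = cens_frac > 0.5))
}

# -- robust regression on order statistics (ROS) -----------------------------

# Hirsch-Stedinger plotting positions for a single censoring limit below
# all detects: the exceedance probability of the limit is d/n, detects get
# cumulative positions c/n + (d/n) * i/(d+1) (i = 1..d, ascending) and
# nondetects get (c/n) * j/(c+1) (j = 1..c).
hs_plotting_positions <- function(n_detect, n_cens) {
  n <- n_detect + n_cens
  pe <- n_detect / n
  list(detect = (1 - pe) + pe * seq_len(n_detect) / (n_detect + 1),
       censored = if (n_cens > 0) (1 - pe) * seq_len(n_cens) / (n_cens + 1)
                  else numeric(0))
}

fit_ros <- function(sample) {
  det <- sort(detected_values(sample))
  d <- length(det)
  cc <- n_censored(sample)
  if (d < 3)
    stop_lcens("ROS needs at least 3 detected values", "lcens_insufficient_data")
  pp <- hs_plotting_positions(d, cc)
  q <- stats::qnorm(pp$detect)
  ly <- log(det)
  slope <- stats::cov(q, ly) / stats::var(q)
  intercept <- mean(ly) - slope * mean(q)
  flag_floor <- FALSE
  flag_cap <- FALSE
  imputed <- numeric(0)
  if (cc > 0) {
    imputed <- exp(intercept + slope * stats::qnorm(pp$censored))
    if (any(imputed <= 0)) { # exp() can underflow to 0
      imputed[imputed <= 0] <- .Machine$double.xmin
      flag_floor <- TRUE
    }
    rl <- effective_rl(sample)
    if (any(imputed > rl)) { # imputations must stay in the censored region
      imputed[imputed > rl] <- rl
      flag_cap <- TRUE
    }
  }
  combined <- c(imputed, det)
  est <- plain_stats(combined)
  list(estimates = est,
       params = lnorm_params(meanlog = log(est[["gm"]]), sdlog = log(est[["gsd"]])),
       meta = list(ros = list(plotting_positions = pp,
                              slope = slope, intercept = intercept,
                              imputed_values = imputed, combined = combined,
                              floored = flag_floor, capped = flag_cap)))
}

# -- censored maximum likelihood ---------------------------------------------

# log-likelihood of Eq.-(1)-type censored lognormal data via sufficient
# statistics of the log detects; th = (meanlog, log sdlog)
censored_lnorm_loglik <- function(meanlog, sdlog, sample) {
  det <- detected_values(sample)
  lx <- log(det)
  d <- length(lx)
  cc <- n_censored(sample)
  ll <- sum(stats::dnorm(lx, meanlog, sdlog, log = TRUE)) - sum(lx)
  if (cc > 0) {
    rl <- effective_rl(sample)
    ll <- ll + cc * stats::pnorm((log(rl) - meanlog) / sdlog, log.p = TRUE)
  }
  ll
}

fit_mle <- function(sample) {
  det <- detected_values(sample)
  d <- length(det)
  if (d < 2)
    stop_lcens("MLE needs at least 2 detected values", "lcens_insufficient_data")
  cc <- n_censored(sample)
  lx <- log(det)
  S1 <- sum(lx); S2 <- sum(lx^2)
  lrl <- log(effective_rl(sample))
  nll <- function(th) {
    m <- th[1]; s <- exp(th[2])
    v <- (S2 - 2 * m * S1 + d * m^2) / (2 * s^2)
    out <- d * th[2] + 0.5 * d * log(2 * pi) + v + S1
    if (cc > 0) out <- out - cc * stats::pnorm((lrl - m) / s, log.p = TRUE)
    out
  }
  grad <- function(th) {
    m <- th[1]; s <- exp(th[2])
    ss <- S2 - 2 * m * S1 + d * m^2
    gm_ <- -(S1 - d * m) / s^2
    gs_ <- d - ss / s^2 # d/dlog s
    if (cc > 0) {
      z <- (lrl - m) / s
      h <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
      gm_ <- gm_ + cc * h / s
      gs_ <- gs_ + cc * h * z
    }
    c(gm_, gs_)
  }
  # two starts: uncensored closed form on detects, substitution-based moments
  m0 <- mean(lx)
  s0 <- sqrt(mean((lx - m0)^2))
  starts <- list(c(m0, log(max(s0, 1e-3))))
  if (cc > 0 && !is.na(sample$rl)) {
    sub <- log(c(det, rep(0.5 * sample$rl, cc)))
    starts <- c(starts, list(c(mean(sub), log(max(stats::sd(sub), 1e-3)))))
  }
  fits <- lapply(starts, function(st)
    tryCatch(stats::optim(st, nll, gr = grad, method = "BFGS",
                          control = list(reltol = 1e-12, maxit = 500)),
             error = function(e) NULL))
  fits <- Filter(function(f) !is.null(f) && f$convergence == 0, fits)
  if (!length(fits))
    stop_lcens("censored MLE failed to converge from all starts",
               "lcens_estimation_failure")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  gnorm <- sqrt(sum(grad(best$par)^2))
  params <- lnorm_params(meanlog = best$par[1], sdlog = exp(best$par[2]))
  mo <- lnorm_moments(params)
  list(estimates = c(gm = exp(params$meanlog), gsd = exp(params$sdlog),
                     mean = mo[["mean"]], sd = mo[["sd"]]),
       params = params,
       meta = list(loglik = -best$value, gradient_norm = gnorm,
                   n_starts = length(starts), converged = TRUE))
}

fit_method <- function(sample, method, sub_fraction = 0.5) {
  switch(method,
         dn = fit_dn(sample),
         rl2 = fit_substitution(sample, fraction = sub_fraction),
         km = fit_km(sample),
         ros = fit_ros(sample),
         mle = fit_mle(sample),
         stop_lcens(paste("unknown method:", method), "lcens_domain_error"))
}
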