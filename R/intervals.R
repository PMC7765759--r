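#' Cox's confidence interval for a lognormal mean
#'
#' For log-scale values `y` with mean `ybar` and variance `s2` (n-1
#' denominator), the log of the arithmetic mean is estimated by
#' `theta = ybar + s2/2` with standard error
#' `sqrt(s2/n + s2^2/(2*(n-1)))`; the interval is `exp(theta +/- z * se)`.
#' Used for the mean under the discard-nondetects and substitution
#' estimators.
#'
#' @param log_values Numeric vector of log concentrations (n >= 2, finite).
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Named numeric vector `c(lci, uci)`.
#' @export
cox_ci <- function(log_values, level = 0.95) {
  if (length(log_values) < 2)
    stop_lcens("Cox's method needs at least 2 values", "lcens_insufficient_data")
  if (any(!is.finite(log_values)))
    stop_lcens("log values must be finite", "lcens_invalid_parameter")
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop_lcens("level must lie in (0, 1)", "lcens_invalid_parameter")
  n <- length(log_values)
  ybar <- mean(log_values)
  s2 <- stats::var(log_values)
  theta <- ybar + s2 / 2
  se <- sqrt(s2 / n + s2^2 / (2 * (n - 1)))
  z <- stats::qnorm((1 + level) / 2)
  c(lci = exp(theta - z * se), uci = exp(theta + z * se))
}

# bootstrap resample index matrix: one root seed fans out into one substream
# per replicate, so results are reproducible and order-invariant
bootstrap_indices <- function(n, reps, seed = NULL) {
  seeds <- derive_seeds(seed, reps)
  t(vapply(seeds, function(s) with_seed(s, sample.int(n, n, replace = TRUE)),
           integer(n)))
}

#' BCa bootstrap confidence interval for the mean
#'
#' Nonparametric bias-corrected and accelerated bootstrap for the mean
#' estimated by the KM, ROS or MLE method on a left-censored sample.
#' Observations are resampled as (value, censoring flag) pairs and, by
#' default, the reporting limit is recomputed per replicate as the minimum
#' resampled detect (the same convention the estimators use on the original
#' sample). The bias-correction `z0` is the normal quantile of the fraction
#' of replicate statistics below the point estimate (ties count half), and
#' the acceleration `a` is the jackknife skewness of the statistic.
#'
#' @param sample A [censored_sample].
#' @param method One of `"km"`, `"ros"`, `"mle"` (any `fit` method works).
#' @param level Confidence level, default 0.95.
#' @param reps Number of bootstrap replicates (>= 100), default 1000.
#' @param seed Optional integer seed; given the seed the interval is
#'   deterministic.
#' @param fixed_rl If `TRUE`, keep the original sample's reporting limit in
#'   every replicate instead of recomputing it. Default `FALSE`.
#' @param indices Optional `reps x n` integer matrix of resample indices
#'   (overrides `reps`/`seed`); exposed so an independent implementation can
#'   be run on the identical resample stream.
#' @return Named numeric vector `c(lci, uci)` with attributes `z0`, `a`,
#'   and `n_failed`.
#' @export
bootstrap_bca_ci <- function(sample, method, level = 0.95, reps = 1000,
                             seed = NULL, fixed_rl = FALSE, indices = NULL) {
  stopifnot(inherits(sample, "censored_sample"))
  if (is.null(indices)) {
    if (reps < 100)
      stop_lcens("at least 100 bootstrap replicates required",
                 "lcens_invalid_parameter")
    indices <- bootstrap_indices(sample$n, reps, seed)
  }
  stat <- function(values, censored) {
    s <- censored_sample(values, censored,
                         rl = if (fixed_rl) sample$rl else NULL)
    fit_method(s, method)$estimates[["mean"]]
  }
  t0 <- stat(sample$values, sample$censored)
  t_boot <- apply(indices, 1, function(idx)
    tryCatch(stat(sample$values[idx], sample$censored[idx]),
             error = function(e) NA_real_))
  n_failed <- sum(is.na(t_boot))
  if (n_failed > 0.2 * length(t_boot))
    stop_lcens(sprintf("%d of %d bootstrap replicates failed",
                       n_failed, length(t_boot)), "lcens_interval_failure")
  t_boot <- t_boot[!is.na(t_boot)]
  if (all(t_boot == t_boot[1])) {
    warn_lcens("all bootstrap replicates identical; degenerate interval",
               "lcens_degenerate_interval")
    return(structure(c(lci = t_boot[1], uci = t_boot[1]),
                     z0 = 0, a = 0, n_failed = n_failed))
  }
  # jackknife acceleration
  jack <- vapply(seq_len(sample$n), function(i)
    tryCatch(stat(sample$values[-i], sample$censored[-i]),
             error = function(e) NA_real_), numeric(1))
  jack <- jack[!is.na(jack)]
  dj <- mean(jack) - jack
  a <- if (sum(dj^2) > 0) sum(dj^3) / (6 * sum(dj^2)^1.5) else 0
  # bias correction with continuity correction at ties
  pb <- (sum(t_boot < t0) + 0.5 * sum(t_boot == t0)) / length(t_boot)
  pb <- min(max(pb, 1 / (2 * length(t_boot))), 1 - 1 / (2 * length(t_boot)))
  z0 <- stats::qnorm(pb)
  bounds <- bca_bounds(t_boot, z0, a, level)
  structure(bounds, z0 = z0, a = a, n_failed = n_failed)
}

# adjusted percentile bounds shared with the test oracle's formulas;
# quantiles of the replicate distribution use the median-unbiased rule
bca_bounds <- function(t_boot, z0, a, level) {
  alpha <- c((1 - level) / 2, (1 + level) / 2)
  za <- stats::qnorm(alpha)
  adj <- stats::pnorm(z0 + (z0 + za) / (1 - a * (z0 + za)))
  q <- quantile_mu(t_boot, adj)
  c(lci = q[1], uci = q[2])
}
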