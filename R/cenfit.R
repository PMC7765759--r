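#' Fit summary statistics to a left-censored concentration sample
#'
#' The package's central fitting function. Given a sample of positive
#' concentrations in which some observations are nondetects, estimates the
#' geometric mean (GM), geometric standard deviation (GSD), arithmetic mean
#' and SD of the underlying lognormal distribution, with a 95% interval for
#' the mean, by one of six methods:
#'
#' * `"dn"` — discard nondetects; statistics of the detects only.
#' * `"rl2"` — substitute `sub_fraction * RL` (default half the reporting
#'   limit) for each nondetect.
#' * `"km"` — Kaplan-Meier product-limit estimate through the flip
#'   transform; the mean is the area beneath the estimated CDF, GM/GSD come
#'   from the same CDF applied to log values, and the unresolved mass below
#'   the smallest detect is assigned to the smallest detect.
#' * `"ros"` — robust regression on order statistics: nondetects are
#'   imputed from a lognormal Q-Q regression of the detects at
#'   Hirsch-Stedinger plotting positions, and statistics are computed from
#'   detects plus imputations.
#' * `"mle"` — censored maximum likelihood: detects contribute the
#'   lognormal density and the nondetect count multiplies the log CDF at
#'   the reporting limit.
#' * `"mcmc"` — the Bayesian censored model: like the MLE likelihood but
#'   with the reporting limit treated as a parameter supported on
#'   (0, min detect], sampled by MCMC; point estimates are expected a
#'   posteriori (EAP) means of the per-draw quantities.
#'
#' Intervals follow the method (`interval = "auto"`): Cox's method for
#' dn/rl2, BCa bootstrap for km/ros/mle, an equal-tailed credible interval
#' for mcmc.
#'
#' @param x A [censored_sample], or a numeric vector (combined with
#'   `censored`).
#' @param censored Logical vector of nondetect flags when `x` is numeric.
#' @param rl Reporting limit when `x` is numeric (default: minimum detect).
#' @param method One of `"mcmc"`, `"mle"`, `"km"`, `"ros"`, `"dn"`, `"rl2"`.
#' @param interval `"auto"`, `"cox"`, `"bca"`, `"credible"`, or `"none"`.
#' @param conf_level Interval level, default 0.95.
#' @param boot_reps Bootstrap replicates for BCa intervals.
#' @param seed Optional seed (bootstrap resampling / MCMC).
#' @param sub_fraction Substitution fraction for `"rl2"`.
#' @param priors A [prior_spec] for `"mcmc"` (default [prior_spec]`(x)`).
#' @param mcmc An [mcmc_config] for `"mcmc"`.
#' @return An object of class `"cenfit"` with components `method`,
#'   `sample`, `estimates` (gm, gsd, mean, sd), `params` (a [lnorm_params]
#'   view of gm/gsd), `ci` (lci, uci, level, type) and `meta` (diagnostics:
#'   ROS imputations, MCMC draws and R-hat, optimizer trace, ...).
#' @examples
#' x <- censored_sample(c(0.2, 0.5, 1, 2, 5, rep(NA, 5)),
#'                      censored = rep(c(FALSE, TRUE), each = 5))
#' cenfit(x, method = "mle", interval = "none")
#' @export
cenfit <- function(x, censored = NULL, rl = NULL,
                   method = c("mcmc", "mle", "km", "ros", "dn", "rl2"),
                   interval = c("auto", "cox", "bca", "credible", "none"),
                   conf_level = 0.95, boot_reps = 1000, seed = NULL,
                   sub_fraction = 0.5, priors = NULL, mcmc = mcmc_config()) {
  method <- match.arg(method)
  interval <- match.arg(interval)
  sample <- if (inherits(x, "censored_sample")) x
            else censored_sample(x, censored, rl)
  if (interval == "auto")
    interval <- switch(method, dn = "cox", rl2 = "cox", mcmc = "credible", "bca")
  meta <- list()
  if (method == "mcmc") {
    if (!is.null(seed) && is.null(mcmc$seed)) mcmc$seed <- seed
    draws <- sample_posterior(sample, priors = priors, config = mcmc)
    estimates <- c(gm = eap(draws, "gm"), gsd = eap(draws, "gsd"),
                   mean = eap(draws, "mean"), sd = eap(draws, "sd"))
    params <- lnorm_params(meanlog = eap(draws, "meanlog"),
                           sdlog = eap(draws, "sdlog"))
    meta <- list(draws = draws, rhat = attr(draws, "rhat"),
                 ess = attr(draws, "ess"), rl_eap = eap(draws, "rl"),
                 convergence_warning = attr(draws, "convergence_warning"))
  } else {
    fit <- fit_method(sample, method, sub_fraction = sub_fraction)
    estimates <- fit$estimates
    params <- fit$params
    meta <- fit$meta
  }
  ci <- c(lci = NA_real_, uci = NA_real_)
  if (interval == "cox") {
    lv <- switch(method,
                 dn = log(detected_values(sample)),
                 rl2 = {
                   full <- sample$values
                   full[sample$censored] <- sub_fraction * effective_rl(sample)
                   log(full)
                 },
                 log(detected_values(sample)))
    ci <- cox_ci(lv, conf_level)
  } else if (interval == "bca") {
    if (method %in% c("dn", "rl2", "mcmc"))
      stop_lcens("BCa intervals are provided for km/ros/mle fits",
                 "lcens_invalid_parameter")
    ci <- bootstrap_bca_ci(sample, method, level = conf_level,
                           reps = boot_reps, seed = seed)
    meta$bca <- attributes(ci)[c("z0", "a", "n_failed")]
    ci <- c(lci = ci[["lci"]], uci = ci[["uci"]])
  } else if (interval == "credible") {
    if (method != "mcmc")
      stop_lcens("credible intervals require method = 'mcmc'",
                 "lcens_invalid_parameter")
    ci <- credible_interval(meta$draws, "mean", conf_level)
  }
  structure(list(method = method, sample = sample, estimates = estimates,
                 params = params,
                 ci = list(lci = ci[["lci"]], uci = ci[["uci"]],
                           level = conf_level, type = interval),
                 meta = meta),
            class = c(paste0("cenfit_", method), "cenfit"))
}

method_label <- function(method) {
  c(dn = "DN", rl2 = "RL/2", km = "KM", ros = "ROS", mle = "MLE",
    mcmc = "MCMC")[[method]]
}

#' @export
print.cenfit <- function(x, digits = 4, ...) {
  s <- x$sample
  cat(sprintf("Left-censored lognormal fit (%s)\n", method_label(x$method)))
  cat(sprintf("n = %d (%d censored, RL = %s)\n", s$n, sum(s$censored),
              format(effective_rl(s), digits = digits)))
  e <- x$estimates
  cat(sprintf("  GM = %.*g  GSD = %.*g\n", digits, e[["gm"]], digits, e[["gsd"]]))
  cat(sprintf("  mean = %.*g  SD = %.*g\n", digits, e[["mean"]], digits, e[["sd"]]))
  if (!is.na(x$ci$lci))
    cat(sprintf("  %d%% %s interval for the mean: [%.*g, %.*g]\n",
                round(100 * x$ci$level), x$ci$type, digits, x$ci$lci,
                digits, x$ci$uci))
  invisible(x)
}

#' @export
summary.cenfit <- function(object, ...) {
  out <- list(fit = object,
              row = data.frame(method = method_label(object$method),
                               mean = object$estimates[["mean"]],
                               sd = object$estimates[["sd"]],
                               lci = object$ci$lci, uci = object$ci$uci,
                               gm = object$estimates[["gm"]],
                               gsd = object$estimates[["gsd"]]))
  if (object$method == "mcmc") {
    out$rhat <- object$meta$rhat
    out$ess <- object$meta$ess
    out$rl_eap <- object$meta$rl_eap
  }
  class(out) <- "summary.cenfit"
  out
}

#' @export
print.summary.cenfit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  if (!is.null(x$rhat)) {
    cat("convergence (split R-hat):",
        paste(sprintf("%s %.3f", names(x$rhat), x$rhat), collapse = ", "), "\n")
    cat(sprintf("EAP reporting limit: %.*g\n", digits, x$rl_eap))
  }
  invisible(x)
}

#' @export
coef.cenfit <- function(object, ...) {
  out <- c(meanlog = object$params$meanlog, sdlog = object$params$sdlog)
  if (object$method == "mcmc") out <- c(out, rl = object$meta$rl_eap)
  out
}

#' @export
confint.cenfit <- function(object, parm = "mean", level = NULL, ...) {
  if (!identical(parm, "mean"))
    stop_lcens("intervals are computed for the mean only", "lcens_domain_error")
  if (is.null(level) || isTRUE(all.equal(level, object$ci$level)))
    return(c(lci = object$ci$lci, uci = object$ci$uci))
  if (object$method == "mcmc")
    return(credible_interval(object$meta$draws, "mean", level))
  stop_lcens("refit with the desired conf_level to change a frequentist interval",
             "lcens_domain_error")
}

#' Simulate concentrations from a fitted model
#'
#' For an MCMC fit, draws from the posterior-predictive distribution
#' (lognormal variates generated per retained draw); for the other methods,
#' lognormal variates at the fitted GM/GSD.
#'
#' @param object A `cenfit` object.
#' @param nsim Number of values (for mcmc, rounded up to a multiple of the
#'   retained draw count's per-draw share).
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Numeric vector of simulated concentrations.
#' @export
simulate.cenfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$method == "mcmc") {
    draws <- object$meta$draws
    per <- ceiling(nsim / nrow(draws))
    return(posterior_predictive(draws, per_draw = per, seed = seed)[seq_len(nsim)])
  }
  with_seed(seed, stats::rlnorm(nsim, object$params$meanlog, object$params$sdlog))
}

#' Quantiles of a fitted distribution
#'
#' Lognormal quantiles at the fitted parameters; for a KM fit, the
#' quantile is read from the estimated discrete CDF instead.
#'
#' @param x A `cenfit` object.
#' @param probs Probabilities strictly inside (0, 1).
#' @param ... Unused.
#' @export
quantile.cenfit <- function(x, probs = c(0.025, 0.5, 0.975), ...) {
  if (x$method == "km") {
    cdf <- x$meta$cdf
    cum <- cumsum(cdf$w)
    return(stats::setNames(
      vapply(probs, function(p) cdf$x[which(cum >= p - 1e-12)[1]], numeric(1)),
      paste0(100 * probs, "%")))
  }
  stats::setNames(lnorm_quantile(x$params, probs), paste0(100 * probs, "%"))
}

#' Plot a censored-data fit
#'
#' Empirical CDF of the sample (the KM discrete CDF, which handles the
#' censored mass) with the fitted lognormal CDF overlaid on a log
#' concentration axis.
#'
#' @param x A `cenfit` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cenfit <- function(x, ...) {
  cdf <- km_cdf(x$sample)
  cum <- cumsum(cdf$w)
  graphics::plot(cdf$x, cum, log = "x", type = "s",
                 xlab = paste0("concentration",
                               if (!is.null(x$sample$unit))
                                 paste0(" (", x$sample$unit, ")") else ""),
                 ylab = "cumulative probability", ylim = c(0, 1), ...)
  xs <- exp(seq(log(min(cdf$x)) - 2, log(max(cdf$x)) + 1, length.out = 200))
  graphics::lines(xs, stats::plnorm(xs, x$params$meanlog, x$params$sdlog),
                  col = 2)
  graphics::legend("topleft", bty = "n", lty = 1, col = c(1, 2),
                   legend = c("empirical (product-limit)",
                              paste("fitted lognormal,", method_label(x$method))))
  invisible(x)
}

#' Fit several methods and tabulate the results
#'
#' Convenience wrapper producing one row per method with columns
#' Mean, SD, LCI, UCI, GM, GSD.
#'
#' @param x A [censored_sample] (or numeric vector, see [cenfit()]).
#' @param methods Methods to fit.
#' @param ... Passed to [cenfit()].
#' @return Data frame, one row per method; failed fits carry `NA`s and the
#'   error message in the `note` column.
#' @export
estimate_table <- function(x, methods = c("dn", "rl2", "km", "ros", "mle", "mcmc"),
                           ...) {
  rows <- lapply(methods, function(m) {
    fit <- tryCatch(cenfit(x, method = m, ...), error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(method = method_label(m), mean = NA_real_,
                        sd = NA_real_, lci = NA_real_, uci = NA_real_,
                        gm = NA_real_, gsd = NA_real_,
                        note = conditionMessage(fit)))
    cbind(summary(fit)$row, note = "")
  })
  do.call(rbind, rows)
}
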