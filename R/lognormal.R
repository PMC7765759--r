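#' Lognormal parameters in three equivalent views
#'
#' A lognormal distribution is parameterized internally by `meanlog` and
#' `sdlog` (the mean and SD of the log-scale normal). Two derived views are
#' used throughout the package: the geometric mean/geometric standard
#' deviation, `gm = exp(meanlog)`, `gsd = exp(sdlog)`, and the arithmetic
#' moments, `mean = gm * exp(log(gsd)^2 / 2)`,
#' `sd = mean * sqrt(exp(log(gsd)^2) - 1)`. All fitting is done on the log
#' scale where the numerics are stable; GM/GSD and mean/SD are conversions.
#'
#' `sdlog = 0` (`gsd = 1`) is permitted as the degenerate point-mass case.
#'
#' @param meanlog Log-scale mean (log concentration).
#' @param sdlog Log-scale standard deviation, `>= 0`.
#' @param gm,gsd Geometric mean (`> 0`) and geometric standard deviation
#'   (`>= 1`); an alternative way to specify the same distribution.
#' @return An object of class `"lnorm_params"`: a list with elements
#'   `meanlog` and `sdlog`.
#' @examples
#' p <- lnorm_params(gm = 0.082e-3, gsd = 4.9)
#' lnorm_moments(p)
#' lnorm_quantile(p, 0.5) # the median is the GM
#' @export
lnorm_params <- function(meanlog = NULL, sdlog = NULL, gm = NULL, gsd = NULL) {
  if (!is.null(gm)) {
    if (!is.null(meanlog))
      stop_lcens("supply either (meanlog, sdlog) or (gm, gsd), not both",
                 "lcens_invalid_parameter")
    if (!is.finite(gm) || gm <= 0)
      stop_lcens("gm must be finite and > 0", "lcens_invalid_parameter")
    meanlog <- log(gm)
    if (!is.null(gsd)) {
      if (!is.finite(gsd) || gsd < 1)
        stop_lcens("gsd must be finite and >= 1", "lcens_invalid_parameter")
      sdlog <- log(gsd)
    }
  }
  if (is.null(meanlog) || is.null(sdlog))
    stop_lcens("both parameters of the lognormal must be given",
               "lcens_invalid_parameter")
  if (!is.finite(meanlog) || !is.finite(sdlog) || sdlog < 0)
    stop_lcens("meanlog must be finite and sdlog finite and >= 0",
               "lcens_invalid_parameter")
  structure(list(meanlog = as.numeric(meanlog), sdlog = as.numeric(sdlog)),
            class = "lnorm_params")
}

#' @export
print.lnorm_params <- function(x, digits = 4, ...) {
  mo <- lnorm_moments(x)
  cat("Lognormal parameters\n")
  cat(sprintf("  meanlog = %.*g, sdlog = %.*g\n", digits, x$meanlog, digits, x$sdlog))
  cat(sprintf("  GM = %.*g, GSD = %.*g\n", digits, exp(x$meanlog), digits, exp(x$sdlog)))
  cat(sprintf("  mean = %.*g, SD = %.*g\n", digits, mo[["mean"]], digits, mo[["sd"]]))
  invisible(x)
}

#' Arithmetic mean and SD of a lognormal distribution
#'
#' Standard lognormal moment identities: with `g = log(gsd)`,
#' `mean = gm * exp(g^2/2)` and `sd = mean * sqrt(exp(g^2) - 1)`.
#'
#' @param params A [lnorm_params] object.
#' @return Named numeric vector `c(mean, sd)`.
#' @export
lnorm_moments <- function(params) {
  stopifnot(inherits(params, "lnorm_params"))
  v <- params$sdlog^2
  m <- exp(params$meanlog + v / 2)
  s <- m * sqrt(expm1(v))
  c(mean = m, sd = s)
}

#' Lognormal parameters from arithmetic mean and SD
#'
#' Inverse of [lnorm_moments()]: `sdlog = sqrt(log(1 + (sd/mean)^2))`,
#' `meanlog = log(mean) - sdlog^2/2`.
#'
#' @param mean Arithmetic mean, `> 0`.
#' @param sd Arithmetic standard deviation, `>= 0`.
#' @return A [lnorm_params] object.
#' @export
lnorm_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0 || !is.finite(sd) || sd < 0)
    stop_lcens("mean must be > 0 and sd >= 0", "lcens_invalid_parameter")
  v <- log1p((sd / mean)^2)
  lnorm_params(meanlog = log(mean) - v / 2, sdlog = sqrt(v))
}

#' Lognormal quantile
#'
#' Returns `gm * gsd^qnorm(p)`, i.e. `exp(meanlog + sdlog * qnorm(p))`.
#' Used, among other things, to place the censoring threshold at a
#' theoretical percentile of the true distribution in simulations.
#'
#' @param params A [lnorm_params] object.
#' @param p Probability (vectorized), strictly inside (0, 1).
#' @return Concentration quantile(s).
#' @export
lnorm_quantile <- function(params, p) {
  stopifnot(inherits(params, "lnorm_params"))
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop_lcens("p must lie strictly inside (0, 1)", "lcens_domain_error")
  exp(params$meanlog + params$sdlog * stats::qnorm(p))
}
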