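#' A univariate sample with left-censored observations
#'
#' Container for concentration data in which some observations are
#' nondetects: values known only to lie below a reporting limit (RL).
#' Censored entries carry no usable magnitude — any number supplied for a
#' censored position is discarded and stored as `NA`. By the package's
#' convention (shared by the estimators) the reporting limit is the minimum
#' detected value unless an explicit smaller limit is supplied, e.g. parsed
#' from `"<RL"` tokens in a data file.
#'
#' @param values Numeric vector of concentrations (same physical units
#'   throughout, e.g. mg/L). Entries at censored positions may be `NA`.
#' @param censored Logical vector, `TRUE` for nondetects. Default: none.
#' @param rl Reporting limit. Default `NULL` takes the minimum detected
#'   value. Use `NA` to declare the limit unknown (the substitution and
#'   maximum-likelihood estimators then fall back to the minimum detect).
#' @param unit Optional unit label, carried opaquely (never converted).
#' @return An object of class `"censored_sample"`: list with elements
#'   `values`, `censored`, `rl`, `n`, `unit`.
#' @examples
#' x <- censored_sample(c(0.2, 0.5, 1, 2, 5, rep(NA, 5)),
#'                      censored = rep(c(FALSE, TRUE), each = 5))
#' x
#' @export
censored_sample <- function(values, censored = NULL, rl = NULL, unit = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1)
    stop_lcens("a sample needs at least one observation", "lcens_validation")
  if (is.null(censored)) censored <- rep(FALSE, n)
  censored <- as.logical(censored)
  if (length(censored) != n || anyNA(censored))
    stop_lcens("censored must be a logical vector matching values in length",
               "lcens_validation")
  # censored magnitudes are not data: drop them
  values[censored] <- NA_real_
  det <- values[!censored]
  if (length(det) == 0)
    stop_lcens("all observations are censored; at least one detect is required",
               "lcens_all_censored")
  bad <- which(!censored & (!is.finite(values) | values <= 0))
  if (length(bad))
    stop_lcens(paste0("detected values must be finite and > 0; offending rows: ",
                      paste(bad, collapse = ", ")), "lcens_validation")
  if (is.null(rl)) rl <- min(det)
  if (!is.na(rl)) {
    if (!is.finite(rl) || rl <= 0)
      stop_lcens("reporting limit must be positive", "lcens_validation")
    if (any(det < rl))
      stop_lcens("detected values below the reporting limit", "lcens_validation")
  }
  structure(list(values = values, censored = censored, rl = as.numeric(rl),
                 n = n, unit = unit),
            class = "censored_sample")
}

#' @export
print.censored_sample <- function(x, ...) {
  cat(sprintf("Left-censored sample: n = %d (%d detected, %d censored)\n",
              x$n, sum(!x$censored), sum(x$censored)))
  cat(sprintf("Reporting limit: %s%s\n",
              if (is.na(x$rl)) "unknown" else format(x$rl),
              if (is.null(x$unit)) "" else paste0(" ", x$unit)))
  invisible(x)
}

#' @export
as.data.frame.censored_sample <- function(x, ...) {
  data.frame(value = x$values, censored = as.integer(x$censored))
}

#' @export
length.censored_sample <- function(x) x$n

detected_values <- function(sample) sample$values[!sample$censored]

n_censored <- function(sample) sum(sample$censored)

# RL actually used by estimators: the declared limit, else min detect
effective_rl <- function(sample) {
  if (!is.na(sample$rl)) sample$rl else min(detected_values(sample))
}
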