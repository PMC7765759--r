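# internal helpers: typed conditions, seed handling, numerics

stop_lcens <- function(msg, class, call. = FALSE, ...) {
  stop(structure(
    class = c(class, "lcens_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL, ...)
  ))
}

warn_lcens <- function(msg, class) {
  warning(structure(
    class = c(class, "lcens_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
# seed = NULL evaluates as-is on the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic substream seeds: one root seed fans out to n child seeds so
# replicates are reproducible and order-invariant. seed = NULL draws children
# from the current stream (still usable, just not externally reproducible).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# median-unbiased quantile rule (type 8), used everywhere a quartile or
# empirical quantile of estimates/draws is needed so test oracles can match
quantile_mu <- function(x, probs) {
  stats::quantile(x, probs, type = 8, names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
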