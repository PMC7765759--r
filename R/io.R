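#' CSV dialect for censored concentration data
#'
#' Two file layouts are supported. `"two_column"`: a numeric value column
#' plus a 0/1 (or logical) censoring-flag column. `"token"`: a single
#' column where detects are plain numbers (`"0.25"`) and nondetects carry a
#' prefix token (`"<0.1"`), from which the reporting limit is read.
#'
#' @param mode `"two_column"` or `"token"`.
#' @param value_col Name of the value column.
#' @param flag_col Name of the censoring-flag column (two-column mode).
#' @param token Censoring prefix (token mode), default `"<"`.
#' @return An object of class `"csv_dialect"`.
#' @export
csv_dialect <- function(mode = c("two_column", "token"), value_col = "value",
                        flag_col = "censored", token = "<") {
  mode <- match.arg(mode)
  structure(list(mode = mode, value_col = value_col, flag_col = flag_col,
                 token = token), class = "csv_dialect")
}

#' Read censored concentration data from CSV
#'
#' In token mode the reporting limit is the smaller of the token value and
#' the minimum detect; a warning is raised if they conflict (token RL above
#' the minimum detect). Mixed token limits (multiple distinct RLs) are an
#' error, since the estimators assume a single reporting limit. Censored
#' magnitudes are never used as data.
#'
#' @param path CSV file path.
#' @param dialect A [csv_dialect].
#' @return A [censored_sample].
#' @export
read_censored_csv <- function(path, dialect = csv_dialect()) {
  if (!file.exists(path))
    stop_lcens(paste("no such file:", path), "lcens_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!dialect$value_col %in% names(df))
    stop_lcens(paste0("missing column '", dialect$value_col, "'"),
               "lcens_io_error")
  if (dialect$mode == "two_column") {
    if (!dialect$flag_col %in% names(df))
      stop_lcens(paste0("missing column '", dialect$flag_col, "'"),
                 "lcens_io_error")
    flags <- df[[dialect$flag_col]]
    if (!all(flags %in% c(0, 1, TRUE, FALSE)))
      stop_lcens("censoring flags must be 0/1 or logical", "lcens_io_error")
    return(censored_sample(as.numeric(df[[dialect$value_col]]),
                           censored = as.logical(flags)))
  }
  raw <- trimws(as.character(df[[dialect$value_col]]))
  cens <- startsWith(raw, dialect$token)
  vals <- rep(NA_real_, length(raw))
  vals[!cens] <- as.numeric(raw[!cens])
  if (anyNA(vals[!cens]))
    stop_lcens(paste0("unparseable detected values at rows: ",
                      paste(which(!cens & is.na(vals)), collapse = ", ")),
               "lcens_io_error")
  rl <- NULL
  if (any(cens)) {
    token_rl <- as.numeric(sub(paste0("^", dialect$token), "", raw[cens]))
    if (anyNA(token_rl))
      stop_lcens("unparseable censoring tokens", "lcens_io_error")
    u <- unique(token_rl)
    if (length(u) > 1)
      stop_lcens("multiple distinct reporting limits in censoring tokens",
                 "lcens_multi_rl")
    md <- min(vals[!cens])
    if (u > md)
      warn_lcens(sprintf(paste0("token reporting limit (%g) exceeds the minimum ",
                                "detect (%g); using the smaller"), u, md),
                 "lcens_rl_conflict")
    rl <- min(u, md)
  }
  censored_sample(vals, censored = cens, rl = rl)
}

#' Write censored concentration data to CSV
#'
#' Round-trips with [read_censored_csv()] under the same dialect (in
#' two-column mode the reporting limit is reconstructed as the minimum
#' detect; token mode encodes it explicitly).
#'
#' @param sample A [censored_sample].
#' @param path Output file path.
#' @param dialect A [csv_dialect].
#' @export
write_censored_csv <- function(sample, path, dialect = csv_dialect()) {
  if (dialect$mode == "two_column") {
    df <- data.frame(sample$values, as.integer(sample$censored))
    names(df) <- c(dialect$value_col, dialect$flag_col)
  } else {
    raw <- format(sample$values, trim = TRUE, digits = 15)
    raw[sample$censored] <- paste0(dialect$token,
                                   format(effective_rl(sample), digits = 15))
    df <- data.frame(raw)
    names(df) <- dialect$value_col
  }
  tryCatch(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e)
             stop_lcens(paste("cannot write", path), "lcens_io_error"))
  invisible(path)
}
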