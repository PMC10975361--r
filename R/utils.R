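# Internal helpers: logging and input checks.

st_log <- function(..., level = "INFO", verbose = getOption("stinterp.verbose", TRUE)) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

check_numeric <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x)) abort(sprintf("`%s` must be numeric.", name))
  if (finite && any(!is.finite(x))) abort(sprintf("`%s` contains non-finite values.", name))
  if (positive && any(x <= 0)) abort(sprintf("`%s` must be strictly positive.", name))
  invisible(x)
}

check_cols <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing column(s): %s.", name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Sample skewness and excess kurtosis (moment estimators, b1 and g2).
moment_skewness <- function(x) {
  n <- length(x)
  if (n < 3 || sd(x) == 0) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  mean((x - m)^3) / m2^1.5
}

moment_kurtosis <- function(x) {
  n <- length(x)
  if (n < 4 || sd(x) == 0) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  mean((x - m)^4) / m2^2 - 3
}
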