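#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Decimal rounding as used in rendered report tables (22.75 -> 22.8),
#' as opposed to [base::round()]'s round-half-even. Machine outputs keep
#' full precision; only rendered tables pass through this.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

year_of <- function(date) as.integer(format(date, "%Y"))

jan1 <- function(year) as.Date(sprintf("%d-01-01", year))
dec31 <- function(year) as.Date(sprintf("%d-12-31", year))

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
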