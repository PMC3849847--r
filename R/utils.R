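#' Round half away from zero
#'
#' Commercial rounding as used in published epidemiological tables: ties are
#' rounded away from zero, so `round_half_away(0.15, 1)` is `0.2` and
#' `round_half_away(-0.15, 1)` is `-0.2`. (Base [round()] rounds to even.)
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_away(c(0.25, -0.25, 2.345), 1)
round_half_away <- function(x, digits = 1) {
  scale <- 10^digits
  # small epsilon absorbs floating-point representation error just below .5
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Shift a date back by whole calendar years
#'
#' Same month and day, `years` years earlier; 29 February maps to
#' 28 February in non-leap years. Used to form lookback window boundaries.
#'
#' @param date A `Date` vector.
#' @param years Non-negative integer number of years.
#' @return A `Date` vector.
#' @export
subtract_years <- function(date, years) {
  date %m-% lubridate::years(years)
}

#' @importFrom lubridate %m-%
NULL

# Parse a semicolon-delimited secondary-diagnosis field into a list of
# character vectors; empty string -> character(0).
split_codes <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_codes <- function(code_list) {
  vapply(code_list, paste, character(1), collapse = ";")
}

stopifnot_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a probability in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}
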