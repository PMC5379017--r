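#' Round half away from zero
#'
#' Standard "commercial" rounding: ties go away from zero, so 0.5 -> 1 and
#' -0.5 -> -1.  Used for all reported integer percentages, where base R's
#' round-half-to-even would disagree with the conventional hand rounding of
#' published tables (e.g. 5.5 -> 6, not 5.5 -> 6 vs 5.5 -> 6... base R gives
#' round(0.5) == 0).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 70.37, 79.31))
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Validate that a data frame carries the required columns; the error names
# the first missing column so malformed input tables fail loudly.
check_columns <- function(df, required, what = deparse(substitute(df))) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("`%s` is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Scalar checks used across the package.
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

is_probability <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
}
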