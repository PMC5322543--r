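`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round a percentage half-up to the nearest integer
#'
#' Percentages in summary tables are reported as integers with ties rounded
#' away from zero (90.5 -> 91), the convention used throughout the package's
#' table-shaped outputs.
#'
#' @param num numerator count.
#' @param den denominator count; `NA` is returned when zero.
#' @return integer percentage.
#' @export
pct_half_up <- function(num, den) {
  ifelse(den == 0, NA_real_, floor(100 * num / den + 0.5))
}
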