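#' Round half away from zero
#'
#' Decimal rounding in which a digit of exactly 5 rounds up in magnitude
#' (2.135 -> 2.14), matching how assay percentages and folds are reported.
#' Base R's [round()] rounds half to even instead.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
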