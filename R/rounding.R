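#' Decimal rounding for report tables
#'
#' Rounds on the decimal value, not the binary double: the scaled value is
#' first cleared of floating-point noise (at the 9th decimal) so that a cell
#' whose exact decimal value is a tie (e.g. 2.735 at 2 decimals) is treated as
#' one.  Ties are resolved half-even by default, which is the convention the
#' shipped campaign tables were printed under (their four tie cells round
#' 2.735 to 2.74, 0.135 to 0.14, 1.345 to 1.34 and 0.125 to 0.12); a
#' half-up mode is provided for tables produced under the commercial rule.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2, the report convention).
#' @param mode tie-breaking rule, `"half-even"` (default) or `"half-up"`.
#' @return `x` rounded to `digits` decimals.
#' @examples
#' round_decimal(c(0.1875, 2.735, 1.345))   # 0.19 2.74 1.34
#' round_decimal(1.345, mode = "half-up")   # 1.35
#' @export
round_decimal <- function(x, digits = 2, mode = c("half-even", "half-up")) {
  mode <- match.arg(mode)
  s <- sign(x)
  y <- round(abs(x) * 10^digits, 9)
  f <- y - floor(y)
  tie <- abs(f - 0.5) < 1e-9
  up <- if (mode == "half-up") f >= 0.5 - 1e-9 else
    (!tie & f > 0.5) | (tie & floor(y) %% 2 == 1)
  s * (floor(y) + as.numeric(up)) / 10^digits
}

#' Render numbers as fixed-decimal report cells
#'
#' @inheritParams round_decimal
#' @return character vector, `digits` decimals, e.g. `"0.19"`.
#' @export
format_decimal <- function(x, digits = 2, mode = c("half-even", "half-up")) {
  out <- sprintf(paste0("%.", digits, "f"), round_decimal(x, digits, mode))
  out[is.na(x)] <- NA_character_
  out
}
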