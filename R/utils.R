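# Shared numeric/string helpers.

#' Round half away from zero
#'
#' Fixed-decimal display rounding where a trailing 5 always rounds up
#' (538.42365 -> 538.4237), as mass-spectrometry tables print m/z values.
#' Base `round()` uses round-half-even, which differs on exact .5 boundaries.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 4) {
  scale <- 10^digits
  # tiny relative epsilon so values sitting exactly on a .5 boundary are not
  # pushed down by binary floating-point representation
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Canonicalize gene symbols
#'
#' Trims whitespace and uppercases. No alias mapping is attempted; synonym
#' resolution is the caller's responsibility.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of canonical symbols.
#' @export
canonicalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

# integer-safe derived seed (keeps values < 2^31)
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 1009L) %% 2147483647L
}
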