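#' Round half away from zero
#'
#' Used when averaged fractional event counts must become integer person
#' counts for 2x2 table assembly; base `round()`'s round-half-even rule
#' would make table cells depend on parity.
#'
#' @param x Numeric vector.
#' @return `floor(x + 0.5)` for non-negative `x` (counts are never
#'   negative here).
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

# Population (divide-by-n) z-scores; constant vectors map to all zeros.
.zscale <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
}
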