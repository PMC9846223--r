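# Internal helpers shared across modules.

# 97.5% normal quantile used for every Wald interval in the package, kept at
# the presentation precision (qnorm(0.975) to 7 significant digits).
Z975 <- 1.959964

#' Round half away from zero
#'
#' Presentation rounding used for all published-table comparisons: ties are
#' rounded away from zero (0.125 -> 0.13, -0.125 -> -0.13), unlike base
#' [round()] which rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gsem <- function(...) stop(..., call. = FALSE)

# Back out a link-scale SE from a printed estimate with 95% CI.
# or-scale rows: SE = (ln(hi) - ln(lo)) / (2 * 1.959964); beta rows use the
# CI width directly.
ci_to_se <- function(lo, hi, scale) {
  width <- hi - lo
  or <- scale == "or"
  width[or] <- log(hi[or]) - log(lo[or])
  width / (2 * Z975)
}
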