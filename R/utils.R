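# Internal validation and arithmetic helpers shared across modules.

#' @noRd
check_num <- function(x, name, lower = -Inf, upper = Inf, len = 1L) {
  if (!is.numeric(x) || length(x) != len || any(!is.finite(x)))
    stop(sprintf("`%s` must be a finite numeric of length %d", name, len),
         call. = FALSE)
  if (any(x < lower) || any(x > upper))
    stop(sprintf("`%s` must lie in [%s, %s] (got %s)", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  invisible(x)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.725 -> 0.73 at 2 digits), as a
#' serial readout would print, rather than the IEEE round-half-even rule
#' used by [base::round()].
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @export
#' @examples
#' round_half_up(0.725, 2)  # 0.73, where round(0.725, 2) gives 0.72
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
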