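#' @importFrom rlang abort warn .data %||%
NULL

# Classed conditions so callers (and the CLI) can branch on failure modes
# without string-matching messages.
lf_abort <- function(message, class, ...) {
  abort(message, class = c(paste0("lesionfit3d_error_", class), "lesionfit3d_error"), ...)
}

lf_warn <- function(message, class) {
  warn(message, class = c(paste0("lesionfit3d_warning_", class), "lesionfit3d_warning"))
}

#' Round half away from zero
#'
#' Report-style rounding: halves round away from zero (`round_half_away(0.5)`
#' is 1, `round_half_away(-0.5)` is -1), unlike [base::round()]'s
#' round-half-to-even. Used wherever integer percentages or 2-decimal
#' centimetre/cc values are reported.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, 2.345), digits = 0)
#' round_half_away(61.11)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    lf_abort(sprintf("`%s` must be a single positive finite number.", name), "validation")
  }
  invisible(x)
}
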