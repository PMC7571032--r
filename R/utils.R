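#' Round half away from zero
#'
#' Rounding used for presentation of daily-intake and margin-of-exposure
#' values. Differs from [base::round()], which rounds half to even; survey
#' tables in this field conventionally round 0.5 up in magnitude.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 125.236))
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_bad_arg <- function(msg) stop(msg, call. = FALSE)

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_bad_arg(sprintf("`%s` must be a single non-missing number.", name))
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    abort_bad_arg(sprintf(
      "`%s` must be %s %s (got %s).",
      name, if (strict) ">" else ">=", format(lower), format(x)
    ))
  }
  invisible(x)
}
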