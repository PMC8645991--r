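#' Round half away from zero
#'
#' Presentation rounding used for reported percentages: 78.125 prints as
#' 78.13, not the round-to-even 78.12 of [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mcpc <- function(...) stop(..., call. = FALSE)

check_scalar_int <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < min)
    stop_mcpc(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}
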