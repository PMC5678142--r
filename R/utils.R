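# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Display rounding used for percentage tables: exact halves round up
#' (2.45 -> 2.5), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Classed conditions so callers/tests can distinguish failure modes.
stop_format <- function(msg) abort(msg, class = "kaspcall_format_error")
stop_validation <- function(msg) abort(msg, class = "kaspcall_validation_error")
stop_config <- function(msg) abort(msg, class = "kaspcall_config_error")
stop_quant <- function(msg) abort(msg, class = "kaspcall_quant_error")

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

# Canonical numeric formatting for the plate CSV dialect: 9 significant
# digits, plain decimal notation, no trailing whitespace.
format_rfu <- function(x) {
  formatC(signif(x, 9), format = "fg", digits = 9, width = 1)
}
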