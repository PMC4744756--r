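# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
abort <- function(msg, class = "hairpin_error", data = NULL) {
  cond <- structure(
    class = c(class, "hairpin_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data)
  )
  stop(cond)
}

abort_config  <- function(msg, data = NULL) abort(msg, "hairpin_config_error",  data)
abort_io      <- function(msg, data = NULL) abort(msg, "hairpin_io_error",      data)
abort_compute <- function(msg, data = NULL) abort(msg, "hairpin_compute_error", data)

#' Round half away from zero
#'
#' Report rounding used throughout the package: 0.5 rounds to 1, -0.5 to -1
#' (unlike [base::round()], which rounds half to even). Internal computation
#' is never rounded; this is applied only when rendering tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, 2.345), c(0, 0, 2))
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# format a numeric for a report cell: fixed decimals, NA -> "NA"
fmt_num <- function(x, digits) {
  out <- ifelse(is.na(x), "NA",
                formatC(round_half_away(x, digits), format = "f", digits = digits))
  out
}
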