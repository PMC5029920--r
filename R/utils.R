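#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used when mirroring published tables.
#' Base [round()] rounds half to even, which disagrees with how the reference
#' tables were rounded (e.g. 0.0723 at 2 dp must give 0.07, 1.915 must give 1.92).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(1.373556, 0.0723, 2.675), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# clamp x into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# consistent error style: every validation failure names the offending field
fail_field <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
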