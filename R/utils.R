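#' Round half away from zero
#'
#' Published cost tables round 0.366 to 0.37; base [round()] rounds half to
#' even, so reported quantities go through this helper instead. A small
#' epsilon absorbs binary representation error (e.g. `5.83 * 0.55` stored
#' fractionally below 3.2065).
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return `x` rounded half-away-from-zero to `digits` places
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Round a dollar amount to the cent
#' @param x numeric dollar amounts
#' @return amounts rounded half-away-from-zero to 2 decimals
#' @export
round_cents <- function(x) round_half_up(x, 2)

# days-per-month convention used by every "N months" clause
DAYS_PER_MONTH <- 30L

months_to_days <- function(m) as.integer(round(m * DAYS_PER_MONTH))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) stop(sprintf(...), call. = FALSE)

# derive a per-unit substream seed from a master seed; kept < 2^31
substream_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647)
}
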