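# internal helpers shared across modules

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Round half away from zero
#'
#' Report tables use conventional half-up rounding (2.45 -> 2.5) rather than
#' banker's rounding, matching how validation tables are typically printed.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-12) / m
}

# Derive reproducible sub-seeds below 2^31 from one master seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
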