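#' Round half away from zero
#'
#' Report rounding used throughout the package tables: ties are rounded away
#' from zero (so 0.00005 -> 0.0001 at 4 digits), unlike [base::round()]'s
#' round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 4) {
  p <- 10^digits
  # small epsilon absorbs representation error of values printed at `digits`
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Derive a stage seed from a master seed; kept below 2^31 - 1.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1009 + offset) %% 2147483647L)
}

# Clamp to [lo, hi], returning the number of values moved as an attribute.
clamp <- function(x, lo = 0, hi = 100) {
  n <- sum(x < lo | x > hi, na.rm = TRUE)
  out <- pmin(pmax(x, lo), hi)
  attr(out, "n_clamped") <- n
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
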