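`%||%` <- function(x, y) if (is.null(x)) y else x

stop_bad <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop_bad(msg)
  invisible(TRUE)
}

# fractional day-of-year on the 365-day canonical calendar used throughout
# (leap days are dropped when forcing is looped, so model time is plain days)
doy365 <- function(t) ((t - 1) %% 365) + 1

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
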