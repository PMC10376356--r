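# internal numeric helpers

# round half away from zero, as clinical tables are formatted (R's round()
# is round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# round a dose to the nearest practical increment (half-up on ties)
round_to_increment <- function(x, increment_mg) {
  stopifnot(increment_mg > 0)
  round_half_up(x / increment_mg) * increment_mg
}

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) rlang::abort(msg)
  invisible(NULL)
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    rlang::abort(sprintf("`%s` must be finite and > 0.", name))
  }
  invisible(x)
}

check_non_negative <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    rlang::abort(sprintf("`%s` must be finite and >= 0.", name))
  }
  invisible(x)
}
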