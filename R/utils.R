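# Internal helpers: classed conditions and numeric utilities.

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "pedtape_validation_error", ...)
}

abort_usage <- function(msg, ...) {
  rlang::abort(msg, class = "pedtape_usage_error", ...)
}

abort_io <- function(msg, ...) {
  rlang::abort(msg, class = "pedtape_io_error", ...)
}

# round half away from zero on a grid (base round() is half-to-even, which
# would map e.g. 8.25 kg to 8.2 on a 0.1 grid)
round_to <- function(x, unit) {
  sign(x) * floor(abs(x) / unit + 0.5) * unit
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopifnot_scalar_prob <- function(x, name, lo = 0, hi = 1) {
  if (!is_scalar_number(x) || x <= lo || x >= hi) {
    abort_usage(sprintf("`%s` must be a single number in (%g, %g)", name, lo, hi))
  }
  invisible(x)
}
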