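# internal helpers: validation and seed plumbing

stop_if_not <- function(cond, msg, class = "prrtselect_error") {
  if (!isTRUE(cond)) rlang::abort(msg, class = class)
  invisible(TRUE)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  stop_if_not(
    is.numeric(x) && length(x) == 1L && is.finite(x) && x >= lower && x <= upper,
    sprintf("`%s` must be a single finite number in [%s, %s].", name, lower, upper)
  )
}

# Derive a per-unit seed from a base seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% (.Machine$integer.max - 1L))
}

# Run `expr` under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
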