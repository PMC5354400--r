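# Internal validation helpers shared across modules.

assert_scalar_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name), class = "ductnet_input_error")
  }
  lo_ok <- if (strict_min) x > min else x >= min
  if (!lo_ok || x > max) {
    abort(sprintf("`%s` must lie in %s%s, %s].", name,
                  if (strict_min) "(" else "[", format(min), format(max)),
          class = "ductnet_input_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "ductnet_input_error")
  }
  invisible(as.integer(x))
}

# All generators are pure functions of (parameters, seed): the RNG state is
# scoped to the call and restored afterwards.
with_seed <- function(seed, code) {
  assert_count(seed, "seed")
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- rlang::`%||%`
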