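# Internal helpers shared across modules.

# Boltzmann constant in kJ mol^-1 K^-1 (molar gas constant / 1000).
KB_KJ_MOL_K <- 0.0083145

abort_param <- function(field, msg) {
  rlang::abort(sprintf("invalid parameter `%s`: %s", field, msg),
               class = "junctionmech_parameter_error")
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_param(field, "must be a single finite number")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort_param(field, sprintf(
      "must lie in %s%s, %s%s (got %g)",
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]", x))
  }
  invisible(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    check_number(seed, "seed")
    withr::with_seed(as.integer(seed), expr)
  } else {
    expr
  }
}

`%||%` <- function(x, y) if (is.null(x)) y else x
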