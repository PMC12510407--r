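# internal validation and seed helpers

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE,
                         allow_vector = FALSE) {
  if (!is.numeric(x) || anyNA(x) ||
      (!allow_vector && length(x) != 1L)) {
    abort(sprintf("`%s` must be a non-missing numeric %s.",
                  name, if (allow_vector) "vector" else "scalar"),
          class = "chpwater_invalid_parameter")
  }
  low_ok <- if (strict_lower) all(x > lower) else all(x >= lower)
  upp_ok <- if (strict_upper) all(x < upper) else all(x <= upper)
  if (!low_ok || !upp_ok) {
    abort(sprintf("`%s` must lie in %s%s, %s%s.",
                  name,
                  if (strict_lower) "(" else "[", format(lower),
                  format(upper), if (strict_upper) ")" else "]"),
          class = "chpwater_invalid_parameter")
  }
  invisible(x)
}

# Deterministic per-scan / per-subject seed streams derived from one master
# seed; kept below 2^31 - 1 so they are valid R integer seeds.
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.numeric(master) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.numeric(k) * 8191 + 1) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
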