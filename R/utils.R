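# Internal helpers: structured conditions, local RNG scoping, validators.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("pesca_config_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("pesca_validation_error", "error")))
}

stop_capacity <- function(...) {
  stop(errorCondition(paste0(...), class = c("pesca_capacity_error", "error")))
}

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Derive a per-stage substream seed from a master seed; stays within 32-bit
# integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7907 * k) %% 2147483647)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) ||
      x < min)
    stop_validation("'", name, "' must be a single integer >= ", min)
  as.integer(x)
}

assert_fraction <- function(x, name, lo = 0, hi = 1,
                            lo_open = TRUE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok)
    stop_validation("'", name, "' must be in ",
                    if (lo_open) "(" else "[", lo, ",", hi,
                    if (hi_open) ")" else "]")
  as.numeric(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_validation("'", name, "' must be a single positive number")
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
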