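#' @keywords internal
"_PACKAGE"

# Deterministic 32-bit seed derivation: one base seed fans out into
# independent per-task streams (tau draws, replicate draws, MC draws)
# without any stream ever sharing a set.seed() value.  Pure double
# arithmetic; all intermediates stay below 2^53.
derive_seed <- function(base, ...) {
  idx <- c(...)
  x <- as.double(base) %% 2147483647
  for (i in idx) {
    x <- (x * 69069 + 12345 + (as.double(i) + 1) * 2654435) %% 2147483647
  }
  as.integer(x %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_finite_numeric <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stopf("'%s' must be finite numeric", name)
  invisible(x)
}
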