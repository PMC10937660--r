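#' @keywords internal
"_PACKAGE"

# Relative standard deviation in percent. Returns NA for a zero mean.
rsd_pct <- function(x) {
  m <- mean(x)
  if (!is.finite(m) || m == 0) return(NA_real_)
  100 * stats::sd(x) / m
}

# Geometric mean of a strictly positive vector.
gmean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop_input("%s", msg)

# Deterministic per-purpose seed derived from a base seed; stays < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 7919L) %% 2147483587L
}
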