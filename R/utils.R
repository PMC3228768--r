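# Internal numerical helpers shared across modules.

utils::globalVariables(c("x", "y", "entropy_bits"))

deg2rad <- function(x) x * pi / 180

rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

# Numerically stable log(sum(exp(x))); returns -Inf for all--Inf input.
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Shannon entropy in bits of a probability vector, with 0*log(0) := 0.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stopf("`%s` must be a single finite number in [%s, %s]",
          name, format(lower), format(upper))
  }
  invisible(x)
}
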