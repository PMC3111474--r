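# Internal numeric helpers.

# log(sum(exp(x))) guarded against -Inf and large magnitudes
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp of a matrix
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  fin <- is.finite(m)
  out <- m
  out[fin] <- m[fin] + log(rowSums(exp(x[fin, , drop = FALSE] - m[fin])))
  out
}

# Deterministic child seed from a parent seed and a stream label.
# Keeps derived seeds in [1, 2^31 - 2].
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 48271 + h * 16807) %% (2^31 - 2) + 1)
}

stop_tn <- function(...) stop(..., call. = FALSE)

check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop_tn(sprintf("'%s' must be a single probability in [0, 1]", name))
  invisible(p)
}
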