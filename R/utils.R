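# Internal numerical helpers.

# log(sum(exp(x))) without overflow; returns -Inf for empty/all -Inf input.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp of a matrix (max.col avoids a slow apply()).
row_logsumexp <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  ok <- is.finite(mx)
  out <- mx
  out[ok] <- mx[ok] + log(rowSums(exp(m[ok, , drop = FALSE] - mx[ok])))
  out
}

# Normalize rows of a log-weight matrix into probabilities.
row_softmax <- function(m) {
  lse <- row_logsumexp(m)
  exp(m - lse)
}

# Run `expr` under a fixed seed when one is supplied, leaving the global RNG
# state untouched; otherwise use the current RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a parent seed and a stream index, staying within
# 32-bit integer range. Used so one pipeline seed drives independent stages.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 101 * stream) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
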