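# Small numeric helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Numerically stable logistic function
#' @param x numeric vector or matrix of logits.
#' @return values in (0, 1).
#' @keywords internal
sigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

# log(1 + exp(x)) without overflow
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# Row-wise softmax over a 2-column logit matrix; returns n x 2 weights.
softmax2 <- function(logits) {
  m <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - m)
  e2 <- exp(logits[, 2] - m)
  s <- e1 + e2
  cbind(e1 / s, e2 / s)
}

# Evaluate `expr` under a temporary RNG seed without disturbing the caller's
# RNG stream; with seed = NULL the ambient stream is consumed instead (used
# inside seeded training loops).
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# Derive a bounded child seed from a base seed and a stream index.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %%
               .Machine$integer.max)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Glorot-uniform initialiser for a fan_in x fan_out weight matrix.
glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# Inverted-dropout mask: entries are 0 or 1/(1-p) so expectations match
# evaluation mode.
dropout_mask <- function(nrow, ncol, p) {
  if (p <= 0) return(NULL)
  keep <- matrix(stats::runif(nrow * ncol) >= p, nrow, ncol)
  keep / (1 - p)
}

apply_mask <- function(x, mask) {
  if (is.null(mask)) x else x * mask
}
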