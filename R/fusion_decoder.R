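#' Additive attention weights over the two route views
#'
#' Stacks the topology and similarity embeddings of each node as a 2 x d
#' matrix and scores each view with a small shared network:
#' `w = Softmax(W2 tanh(W1 z_view))` per view, giving two positive weights
#' summing to 1. Works row-wise on matrices (one node per row).
#'
#' @param z_topo,z_sim numeric vectors of length d, or n x d matrices.
#' @param W1 matrix d x a (attention bottleneck); `w2` vector of length a.
#' @param w2 second-stage weight vector.
#' @return n x 2 matrix of weights (a 2-vector input returns a 1 x 2 matrix);
#'   rows sum to 1.
#' @export
attention_weights <- function(z_topo, z_sim, W1, w2) {
  if (is.null(dim(z_topo))) z_topo <- matrix(z_topo, nrow = 1)
  if (is.null(dim(z_sim))) z_sim <- matrix(z_sim, nrow = 1)
  if (!all(dim(z_topo) == dim(z_sim))) stopf("view dimensions differ")
  if (nrow(W1) != ncol(z_topo)) stopf("W1 rows (%d) != view dim (%d)",
                                      nrow(W1), ncol(z_topo))
  l1 <- tanh(z_topo %*% W1) %*% w2
  l2 <- tanh(z_sim %*% W1) %*% w2
  softmax2(cbind(l1, l2))
}

#' Attention-weighted fusion of the two views
#'
#' `z = Dropout(w1 * z_topo + w2 * z_sim)`; dropout (inverted scaling) only
#' when `training = TRUE`.
#'
#' @inheritParams attention_weights
#' @param w n x 2 matrix (or 2-vector) of per-node view weights, rows
#'   summing to 1.
#' @param dropout_rate probability in \[0, 1).
#' @param rng_seed optional seed for the dropout mask.
#' @param training logical.
#' @return fused matrix of the same shape as the views.
#' @export
fuse_views <- function(z_topo, z_sim, w, dropout_rate = 0, rng_seed = NULL,
                       training = FALSE) {
  if (is.null(dim(z_topo))) z_topo <- matrix(z_topo, nrow = 1)
  if (is.null(dim(z_sim))) z_sim <- matrix(z_sim, nrow = 1)
  if (is.null(dim(w))) w <- matrix(w, nrow = 1)
  if (any(abs(rowSums(w) - 1) > 1e-8)) stopf("view weights must sum to 1")
  z <- z_topo * w[, 1] + z_sim * w[, 2]
  if (training && dropout_rate > 0) {
    mask <- with_seed_opt(rng_seed, dropout_mask(nrow(z), ncol(z), dropout_rate))
    z <- apply_mask(z, mask)
  }
  z
}

# decoder forward on a matrix of concatenated pair embeddings; returns
# logits and intermediates (used by both scoring and backprop)
decoder_forward <- function(Zp, par) {
  m1 <- sweep(Zp %*% par$dec_W1, 2, par$dec_b1, `+`)
  r1 <- relu(m1)
  m2 <- sweep(r1 %*% par$dec_W2, 2, par$dec_b2, `+`)
  r2 <- relu(m2)
  logit <- drop(r2 %*% par$dec_w3) + par$dec_b3
  list(m1 = m1, r1 = r1, m2 = m2, r2 = r2, logit = logit, Zp = Zp)
}

#' Score a drug-disease pair with the MLP decoder
#'
#' Concatenates the fused drug and disease embeddings and passes them
#' through the three-layer perceptron, returning
#' `s_ij = Sigmoid(MLP([z_i ; z_j]))`. The concatenation is ordered, so
#' swapping arguments generally changes the score.
#'
#' @param z_i fused drug embedding (vector, or matrix of one pair per row).
#' @param z_j fused disease embedding, same shape.
#' @param params decoder parameter list with `dec_W1` (2d x h1), `dec_b1`,
#'   `dec_W2` (h1 x h2), `dec_b2`, `dec_w3` (h2), `dec_b3` (scalar).
#' @return probability (vector) in (0, 1).
#' @export
score_pair <- function(z_i, z_j, params) {
  if (is.null(dim(z_i))) z_i <- matrix(z_i, nrow = 1)
  if (is.null(dim(z_j))) z_j <- matrix(z_j, nrow = 1)
  Zp <- cbind(z_i, z_j)
  if (ncol(Zp) != nrow(params$dec_W1))
    stopf("pair width (%d) != decoder input width (%d)", ncol(Zp), nrow(params$dec_W1))
  unname(drop(sigmoid(decoder_forward(Zp, params)$logit)))
}

#' Mean binary cross-entropy
#'
#' `mean(-(y log s + (1 - y) log(1 - s)))`, evaluated in logit space
#' (`softplus(l) - y l`) for numerical stability; probabilities in `scores`
#' are converted via `qlogis` with clamping.
#'
#' @param scores probabilities in (0, 1), or logits when `logits = TRUE`.
#' @param labels 0/1 vector of the same length.
#' @param logits interpret `scores` as pre-sigmoid logits.
#' @return non-negative scalar.
#' @export
bce_loss <- function(scores, labels, logits = FALSE) {
  if (!length(scores)) stopf("empty input")
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  l <- if (logits) scores else stats::qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12))
  mean(softplus(l) - labels * l)
}
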