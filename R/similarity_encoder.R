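#' One graph-convolution layer
#'
#' The propagation rule `H' = act(A_hat H W + b)` over a symmetrically
#' normalised adjacency with self-loops (see [normalize_adjacency()]).
#'
#' @param H node feature matrix, n x d_in.
#' @param A_hat normalised adjacency, n x n.
#' @param W weight matrix d_in x d_out; `b` bias vector of length d_out.
#' @param b bias vector.
#' @param activation `"relu"` (default) or `"identity"`.
#' @return updated feature matrix n x d_out.
#' @export
gcn_layer <- function(H, A_hat, W, b, activation = "relu") {
  if (ncol(A_hat) != nrow(H)) stopf("A_hat (%d cols) incompatible with H (%d rows)",
                                    ncol(A_hat), nrow(H))
  if (nrow(W) != ncol(H)) stopf("W (%d rows) incompatible with H (%d cols)",
                                nrow(W), ncol(H))
  act <- activation_fun(activation)
  act(sweep((A_hat %*% H) %*% W, 2, b, `+`))
}

#' Two-layer graph convolutions over a pair of similarity graphs
#'
#' Runs one independent two-layer GCN per similarity graph of a single
#' entity type — typically the predefined (Tanimoto / semantic) graph and
#' the embedding-derived kNN graph — over the same node set and returns the
#' two representations.
#'
#' @param features [embedding_matrix()] or matrix of initial node features.
#' @param graphs named list of `similarity_graph`s over the same entities in
#'   the same order (usually `pred` and `feat`).
#' @param params list parallel to `graphs`; each element holds `W1`, `b1`,
#'   `W2`, `b2`. Weights are not shared across graphs unless the caller
#'   passes identical objects.
#' @param activation nonlinearity for both layers.
#' @return named list of n x d_out matrices, one per graph.
#' @export
similarity_encode <- function(features, graphs, params, activation = "relu") {
  X <- if (inherits(features, "embedding_matrix")) features$matrix else features
  ids <- if (inherits(features, "embedding_matrix")) features$entity_ids else rownames(X)
  out <- list()
  for (nm in names(graphs)) {
    g <- graphs[[nm]]
    if (!is.null(ids) && !identical(g$entity_ids, ids))
      stopf("entity order of graph '%s' does not match the feature matrix", nm)
    Ah <- normalize_adjacency(g)
    p <- params[[nm]]
    H1 <- gcn_layer(X, Ah, p$W1, p$b1, activation)
    out[[nm]] <- gcn_layer(H1, Ah, p$W2, p$b2, activation)
  }
  out
}

#' Fuse per-graph similarity representations into one embedding
#'
#' `z_sim = Dropout(ReLU(W_fuse [h_pred ; h_feat] + b_fuse))`, concatenating
#' the per-graph representations row-wise. Dropout (inverted scaling) is
#' active only when `training = TRUE`.
#'
#' @param h_list list of n x d matrices to concatenate (any length >= 1).
#' @param W_fuse matrix `(sum of widths) x d_out`; `b_fuse` length d_out.
#' @param b_fuse bias vector.
#' @param dropout_rate probability in \[0, 1).
#' @param rng_seed optional integer seed for the dropout mask.
#' @param training logical; dropout inactive when `FALSE`.
#' @return n x d_out matrix `z_sim` (non-negative up to dropout scaling).
#' @export
fuse_similarity <- function(h_list, W_fuse, b_fuse, dropout_rate = 0,
                            rng_seed = NULL, training = FALSE) {
  C <- do.call(cbind, h_list)
  if (ncol(C) != nrow(W_fuse))
    stopf("W_fuse rows (%d) != concatenated width (%d)", nrow(W_fuse), ncol(C))
  z <- relu(sweep(C %*% W_fuse, 2, b_fuse, `+`))
  if (training && dropout_rate > 0) {
    mask <- with_seed_opt(rng_seed,
                          dropout_mask(nrow(z), ncol(z), dropout_rate))
    z <- apply_mask(z, mask)
  }
  z
}
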