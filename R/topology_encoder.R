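#' Compose relation weight matrices from shared bases
#'
#' Basis decomposition of the relational weights: each relation's matrix is a
#' coefficient-weighted sum of `B` shared basis matrices,
#' `W_r = sum_b a[r, b] V_b`. With `B` equal to the number of relations and
#' an identity coefficient matrix this recovers unrestricted per-relation
#' weights exactly.
#'
#' @param coeffs numeric matrix, relations x B (a vector is treated as one
#'   relation).
#' @param bases list of B numeric matrices of identical shape.
#' @return list of per-relation weight matrices, named after `rownames(coeffs)`.
#' @export
basis_compose <- function(coeffs, bases) {
  if (is.null(dim(coeffs))) coeffs <- matrix(coeffs, nrow = 1)
  B <- length(bases)
  if (ncol(coeffs) != B)
    stopf("coefficient columns (%d) != number of bases (%d)", ncol(coeffs), B)
  dims <- vapply(bases, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("basis matrices must share one shape")
  out <- vector("list", nrow(coeffs))
  for (r in seq_len(nrow(coeffs))) {
    W <- bases[[1]] * coeffs[r, 1]
    if (B > 1) for (b in 2:B) W <- W + bases[[b]] * coeffs[r, b]
    out[[r]] <- W
  }
  names(out) <- rownames(coeffs)
  out
}

activation_fun <- function(name) {
  switch(name,
         relu = relu,
         identity = identity,
         stopf("unknown activation '%s'", name))
}

#' One relation-aware message-passing layer on the bipartite graph
#'
#' Updates every node embedding by aggregating degree-normalised messages
#' from its neighbours under each relation:
#' `h_v' = act( sum_r sum_{u in N_r(v)} W_r h_u / sqrt(|N_r(u)| |N_r(v)|) )`.
#' Nodes with no neighbours under any relation receive `act(0)`.
#'
#' @param h numeric matrix, `(n_drugs + n_diseases) x d_in`, drugs first.
#' @param g a `bipartite_graph` from [build_bipartite_graph()].
#' @param weights named list of per-relation `d_in x d_out` matrices (one
#'   entry per relation present in the graph's message matrices), e.g. from
#'   [basis_compose()].
#' @param activation `"relu"` (default) or `"identity"`.
#' @param share_directions if `FALSE`, each relation is split into its two
#'   directed halves and `weights` must carry entries named
#'   `<relation>_to_drug` / `<relation>_to_disease`.
#' @return updated node embedding matrix, `n x d_out`.
#' @export
topology_layer <- function(h, g, weights, activation = "relu",
                           share_directions = TRUE) {
  M <- relation_matrices(g, share_directions)
  act <- activation_fun(activation)
  miss <- setdiff(names(M), names(weights))
  if (length(miss)) stopf("missing weight matrix for relation '%s'", miss[1])
  if (nrow(h) != g$n_drugs + g$n_diseases)
    stopf("h has %d rows, graph has %d nodes", nrow(h), g$n_drugs + g$n_diseases)
  P <- 0
  for (r in names(M)) P <- P + (M[[r]] %*% h) %*% weights[[r]]
  act(P)
}

#' Relation-aware topology encoding with layer averaging
#'
#' Applies [topology_layer()] `L` times (layer 1 maps the input width to the
#' shared hidden width; later layers are hidden-to-hidden) and returns the
#' arithmetic mean of the `L` post-layer representations, a multiscale
#' embedding mixing neighbourhood depths. The input `h0` itself is not part
#' of the average.
#'
#' @param h0 initial node feature matrix (drugs stacked over diseases).
#' @param g a `bipartite_graph`.
#' @param weights list of length `L`; element `l` is the per-relation weight
#'   list for layer `l` (all layers `>= 2` must be square so the average is
#'   well defined).
#' @inheritParams topology_layer
#' @return list with `per_layer` (list of the `L` matrices) and `z_topo`
#'   (their mean).
#' @export
topology_encode <- function(h0, g, weights, activation = "relu",
                            share_directions = TRUE) {
  L <- length(weights)
  if (L < 1) stopf("need at least one layer")
  per_layer <- vector("list", L)
  h <- h0
  for (l in seq_len(L)) {
    h <- topology_layer(h, g, weights[[l]], activation, share_directions)
    per_layer[[l]] <- h
  }
  z <- Reduce(`+`, per_layer) / L
  list(per_layer = per_layer, z_topo = z)
}
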