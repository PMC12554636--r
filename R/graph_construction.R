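#' Build the typed bipartite drug-disease training graph
#'
#' Edges carry one of two relation labels: `known` edges are the training
#' positives, and `unknown` edges are a seeded uniform sample of the
#' training-visible unobserved pairs (treated as a distinct relation by the
#' topology encoder, not as ordinary negatives). Pairs outside
#' `fold_train_mask` — i.e. held-out test pairs — never become edges.
#'
#' @param assoc an [association_table()].
#' @param fold_train_mask logical/0-1 matrix of the same shape; `TRUE` marks
#'   pairs whose label may be seen during training. Default: all pairs.
#' @param unknown_sample_size number of unknown-relation edges to sample
#'   (default: one per training positive). Must not exceed the number of
#'   training unknowns.
#' @param rng_seed optional integer; `NULL` consumes the ambient RNG stream.
#' @return object of class `bipartite_graph`: `n_drugs`, `n_diseases`, and
#'   `edges` data.frame with columns `drug`, `disease` (1-based indices) and
#'   `relation`.
#' @export
build_bipartite_graph <- function(assoc, fold_train_mask = NULL,
                                  unknown_sample_size = NULL, rng_seed = NULL) {
  stopifnot(inherits(assoc, "association_table"))
  A <- assoc$matrix
  if (is.null(fold_train_mask)) fold_train_mask <- matrix(TRUE, nrow(A), ncol(A))
  mask <- matrix(as.logical(fold_train_mask), nrow(A), ncol(A))
  pos_idx <- which(mask & A == 1)
  unk_idx <- which(mask & A == 0)
  if (is.null(unknown_sample_size)) unknown_sample_size <- length(pos_idx)
  if (unknown_sample_size > length(unk_idx))
    stopf("unknown_sample_size (%d) exceeds available training unknowns (%d)",
          unknown_sample_size, length(unk_idx))
  samp <- with_seed_opt(rng_seed, {
    if (unknown_sample_size > 0) sample(unk_idx, unknown_sample_size) else integer(0)
  })
  idx <- c(pos_idx, samp)
  rc <- arrayInd(idx, dim(A))
  edges <- data.frame(
    drug = rc[, 1], disease = rc[, 2],
    relation = rep(c("known", "unknown"), c(length(pos_idx), length(samp))),
    stringsAsFactors = FALSE)
  structure(list(n_drugs = nrow(A), n_diseases = ncol(A), edges = edges),
            class = "bipartite_graph")
}

#' Build a weighted k-nearest-neighbour similarity graph
#'
#' Connects each entity to its `k` most similar peers, keeping the raw
#' similarity values as edge weights (no binarisation). With
#' `metric = "cosine"` similarities are cosines of the embedding rows;
#' with `"precomputed"` the values of a [similarity_table()] are used and the
#' diagonal is ignored. Negative cosines are floored at 0 so weights satisfy
#' the non-negativity the symmetric normalisation requires. By default the
#' graph is union-symmetrised: an edge is kept if either endpoint selected
#' the other; `symmetrize = "mutual"` keeps only reciprocal selections.
#'
#' @param features_or_sim an [embedding_matrix()] (cosine) or
#'   [similarity_table()] (precomputed).
#' @param k neighbours per node, `1 <= k < N`.
#' @param metric `"cosine"` or `"precomputed"` (default chosen from input class).
#' @param symmetrize `"union"` or `"mutual"`.
#' @param dense if `TRUE`, skip the top-k sparsification and keep the full
#'   weighted graph (pass-through for predefined similarities).
#' @return object of class `similarity_graph`: `entity_ids`, `weights`
#'   (symmetric non-negative matrix with zero diagonal), `k`, `source`.
#' @export
knn_similarity_graph <- function(features_or_sim, k = 4L,
                                 metric = NULL,
                                 symmetrize = c("union", "mutual"),
                                 dense = FALSE) {
  symmetrize <- match.arg(symmetrize)
  if (inherits(features_or_sim, "similarity_table")) {
    metric <- metric %||% "precomputed"
    stopifnot(metric == "precomputed")
    S <- features_or_sim$matrix
    ids <- features_or_sim$entity_ids
    src <- "predefined"
  } else if (inherits(features_or_sim, "embedding_matrix")) {
    metric <- metric %||% "cosine"
    stopifnot(metric == "cosine")
    X <- features_or_sim$matrix
    nr <- sqrt(rowSums(X^2))
    if (any(nr == 0))
      stopf("zero-norm embedding row for entity '%s' under cosine metric",
            features_or_sim$entity_ids[which(nr == 0)[1]])
    S <- (X / nr) %*% t(X / nr)
    S <- pmax(S, 0)
    ids <- features_or_sim$entity_ids
    src <- "embedding_knn"
  } else stopf("expected an embedding_matrix or similarity_table")
  n <- nrow(S)
  diag(S) <- 0
  if (dense) {
    W <- (S + t(S)) / 2
    return(structure(list(entity_ids = ids, weights = W, k = NULL, source = src),
                     class = "similarity_graph"))
  }
  if (k < 1 || k >= n) stopf("k must satisfy 1 <= k < N (k = %d, N = %d)", k, n)
  sel <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    # ties broken by lower index: order() is stable on ties
    nb <- order(S[i, ], decreasing = TRUE)[seq_len(k)]
    sel[i, nb] <- TRUE
  }
  keep <- if (symmetrize == "union") sel | t(sel) else sel & t(sel)
  W <- S * keep
  W <- (W + t(W)) / 2   # numeric symmetry; values equal where both kept
  structure(list(entity_ids = ids, weights = W, k = as.integer(k), source = src),
            class = "similarity_graph")
}

#' Symmetric normalisation with self-loops
#'
#' Computes `A_hat = D^(-1/2) (A + I) D^(-1/2)` where `D` is the diagonal
#' degree (row-sum) matrix of `A + I`. The self-loop guarantees positive
#' degrees, so the result is always finite; its spectral radius is at
#' most 1.
#'
#' @param g a `similarity_graph` or a symmetric non-negative weight matrix.
#' @return dense symmetric matrix of the same size.
#' @export
normalize_adjacency <- function(g) {
  A <- if (inherits(g, "similarity_graph")) g$weights else as.matrix(g)
  if (max(abs(A - t(A))) > 1e-8) stopf("adjacency must be symmetric")
  if (min(A) < 0) stopf("adjacency must be non-negative")
  Ai <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(Ai))
  Ai * outer(dinv, dinv)
}

#' Randomly drop edges (training-time augmentation)
#'
#' Each edge is removed independently with probability `p`. Meant for
#' training only; evaluation passes always use the intact graph.
#'
#' @param g a `bipartite_graph` or `similarity_graph`.
#' @param p drop probability in \[0, 1\].
#' @param rng_seed optional integer; `NULL` consumes the ambient RNG stream.
#' @return same class as `g`.
#' @export
edge_dropout <- function(g, p, rng_seed = NULL) {
  if (p < 0 || p > 1) stopf("p must lie in [0, 1]")
  if (inherits(g, "bipartite_graph")) {
    keep <- with_seed_opt(rng_seed, stats::runif(nrow(g$edges)) >= p)
    g$edges <- g$edges[keep, , drop = FALSE]
    return(g)
  }
  if (inherits(g, "similarity_graph")) {
    W <- g$weights
    up <- which(upper.tri(W) & W > 0)
    keep <- with_seed_opt(rng_seed, stats::runif(length(up)) >= p)
    W[up[!keep]] <- 0
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    g$weights <- W
    return(g)
  }
  stopf("unsupported graph type")
}

#' Add i.i.d. Gaussian noise to features (training-time augmentation)
#'
#' @param features an [embedding_matrix()] or plain matrix.
#' @param sigma noise standard deviation, `>= 0`.
#' @param rng_seed optional integer; `NULL` consumes the ambient RNG stream.
#' @return same type as `features`.
#' @export
gaussian_perturb <- function(features, sigma, rng_seed = NULL) {
  if (sigma < 0) stopf("sigma must be non-negative")
  m <- if (inherits(features, "embedding_matrix")) features$matrix else features
  if (sigma > 0) {
    noise <- with_seed_opt(rng_seed,
                           matrix(stats::rnorm(length(m), 0, sigma), nrow(m), ncol(m)))
    m <- m + noise
  }
  if (inherits(features, "embedding_matrix")) {
    features$matrix <- m
    features
  } else m
}

# ---- internal: relation message matrices for the topology encoder --------

# Per-relation symmetrically normalised message matrices over the joint node
# set (drugs first, then diseases): M_r[v, u] = 1/sqrt(|N_r(u)| |N_r(v)|) on
# edges of relation r. With share_directions = FALSE each relation is split
# into its two directed halves (drug<-disease and disease<-drug), which the
# encoder then equips with separate weight matrices (the parameter-sharing
# ablation).
relation_matrices <- function(g, share_directions = TRUE) {
  n <- g$n_drugs + g$n_diseases
  rels <- list()
  for (r in c("known", "unknown")) {
    e <- g$edges[g$edges$relation == r, , drop = FALSE]
    M <- matrix(0, n, n)
    if (nrow(e)) {
      di <- e$drug
      mi <- g$n_drugs + e$disease
      deg <- tabulate(c(di, mi), nbins = n)
      w <- 1 / sqrt(deg[di] * deg[mi])
      M[cbind(di, mi)] <- w
      M[cbind(mi, di)] <- w
    }
    if (share_directions) {
      rels[[r]] <- M
    } else {
      Mdm <- M; Mdm[(g$n_drugs + 1):n, ] <- 0  # messages into drug rows
      Mmd <- M; Mmd[1:g$n_drugs, ] <- 0        # messages into disease rows
      rels[[paste0(r, "_to_drug")]] <- Mdm
      rels[[paste0(r, "_to_disease")]] <- Mmd
    }
  }
  rels
}
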