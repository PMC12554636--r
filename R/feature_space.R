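#' Masked mean pooling over token states
#'
#' Collapses a T x D matrix of per-token hidden states to a single D-vector
#' by averaging only the rows whose mask entry is 1 (substantive tokens);
#' padding rows contribute nothing. This is the pooling contract assumed for
#' upstream language-model outputs.
#'
#' @param states numeric T x D matrix of per-token vectors.
#' @param mask 0/1 vector of length T with at least one 1.
#' @return numeric vector of length D.
#' @export
masked_mean_pool <- function(states, mask) {
  states <- as.matrix(states)
  mask <- as.numeric(mask)
  if (length(mask) != nrow(states))
    stopf("mask length (%d) != number of token rows (%d)", length(mask), nrow(states))
  if (!all(mask %in% c(0, 1))) stopf("mask must be 0/1")
  if (sum(mask) < 1) stopf("mask selects no tokens")
  if (any(!is.finite(states))) stopf("token states contain non-finite values")
  colSums(states * mask) / sum(mask)
}

#' Zero-pad an embedding matrix to a wider dimension
#'
#' Appends zero columns so that, e.g., 1024-dimensional small-molecule
#' embeddings can live in the same 1280-dimensional space as protein
#' embeddings. Row norms are unchanged.
#'
#' @param emb an [embedding_matrix()].
#' @param target_dim target width, at least `emb$dim`.
#' @return an [embedding_matrix()] of width `target_dim`.
#' @export
zero_pad <- function(emb, target_dim) {
  stopifnot(inherits(emb, "embedding_matrix"))
  if (target_dim < emb$dim)
    stopf("target_dim (%d) < embedding dim (%d)", target_dim, emb$dim)
  if (target_dim == emb$dim) return(emb)
  m <- cbind(emb$matrix,
             matrix(0, nrow(emb$matrix), target_dim - emb$dim))
  embedding_matrix(m, emb$entity_ids, emb$modality)
}

#' Stack small-molecule and protein drug embeddings into one matrix
#'
#' Unifies the two drug modalities: small-molecule rows are zero-padded to
#' the protein width, then all rows are arranged in the order given by
#' `drug_order`. Every drug must come from exactly one source.
#'
#' @param small_mol [embedding_matrix()] of small-molecule drugs, or `NULL`.
#' @param protein [embedding_matrix()] of protein therapeutics, or `NULL`.
#' @param drug_order character vector giving the output row order.
#' @return an [embedding_matrix()] with `length(drug_order)` rows.
#' @export
stack_drug_features <- function(small_mol = NULL, protein = NULL, drug_order) {
  srcs <- Filter(Negate(is.null), list(small_mol = small_mol, protein = protein))
  if (!length(srcs)) stopf("at least one source matrix required")
  ids <- unlist(lapply(srcs, `[[`, "entity_ids"), use.names = FALSE)
  if (anyDuplicated(ids))
    stopf("drug '%s' appears in more than one source", ids[duplicated(ids)][1])
  missing <- setdiff(drug_order, ids)
  if (length(missing)) stopf("drug '%s' missing from all sources", missing[1])
  width <- max(vapply(srcs, `[[`, numeric(1), "dim"))
  padded <- lapply(srcs, zero_pad, target_dim = width)
  big <- do.call(rbind, lapply(padded, function(e) e$matrix))
  embedding_matrix(big[drug_order, , drop = FALSE], drug_order, "synthetic")
}

#' Fit a PCA and project an embedding matrix onto its top components
#'
#' Centres columns by their mean, computes the singular value decomposition,
#' and projects onto the leading `n_components` principal axes. The sign of
#' each component is fixed so its largest-magnitude loading is positive,
#' making results reproducible across linear-algebra backends. The returned
#' `pca_model` (mean, components, explained variance) lets new entities be
#' projected identically via [project_pca()], which cold-start inference
#' relies on.
#'
#' @param features an [embedding_matrix()] with at least 2 rows.
#' @param n_components requested dimension (default 768). Values above
#'   `min(N, D)` are clamped with a warning so small fixtures still run.
#' @return list with `embedding` (the reduced [embedding_matrix()]) and
#'   `pca_model` (list `mean`, `components` D x k with orthonormal columns,
#'   `explained_variance` non-increasing).
#' @export
fit_pca_reduce <- function(features, n_components = 768L) {
  stopifnot(inherits(features, "embedding_matrix"))
  X <- features$matrix
  n <- nrow(X); d <- ncol(X)
  if (n < 2) stopf("PCA needs at least 2 rows")
  k <- as.integer(n_components)
  if (k < 1) stopf("n_components must be positive")
  if (k > min(n, d)) {
    warnf("n_components = %d clamped to min(N, D) = %d", k, min(n, d))
    k <- min(n, d)
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = k)
  V <- sv$v
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  model <- list(mean = mu, components = V,
                explained_variance = (sv$d[seq_len(k)]^2) / (n - 1))
  list(embedding = embedding_matrix(scores, features$entity_ids, features$modality),
       pca_model = model)
}

#' Project new rows with a previously fitted PCA
#'
#' @param matrix numeric matrix (or vector) in the original feature space.
#' @param pca_model the `pca_model` returned by [fit_pca_reduce()].
#' @return projected matrix with `ncol(pca_model$components)` columns.
#' @export
project_pca <- function(matrix, pca_model) {
  if (is.null(dim(matrix))) matrix <- base::matrix(matrix, nrow = 1)
  m <- as.matrix(matrix)
  if (ncol(m) != length(pca_model$mean))
    stopf("input width (%d) != PCA input width (%d)", ncol(m), length(pca_model$mean))
  sweep(m, 2, pca_model$mean) %*% pca_model$components
}

#' Harmonize drug and disease embeddings into a common feature space
#'
#' Applies [fit_pca_reduce()] to the unified drug matrix (target 768 by
#' default, clamped on small data) and passes disease embeddings through
#' unchanged when their width already matches; otherwise diseases are
#' PCA-reduced to the same width, since the topology encoder stacks drug and
#' disease features into one matrix and needs equal dimensions.
#'
#' @param drugs an [embedding_matrix()] (already stacked across modalities).
#' @param diseases an [embedding_matrix()].
#' @param n_components target dimension for the drug PCA.
#' @return list `drugs`, `diseases` (both [embedding_matrix()]s of equal
#'   width), `pca_model` (drug model), `pca_model_disease` (`NULL` when
#'   diseases were passed through).
#' @export
harmonize_features <- function(drugs, diseases, n_components = 768L) {
  k <- min(n_components, nrow(drugs$matrix), drugs$dim)
  if (diseases$dim != k)    # diseases must be reduced too: clamp jointly
    k <- min(k, nrow(diseases$matrix), diseases$dim)
  fit <- fit_pca_reduce(drugs, k)
  dis_model <- NULL
  if (diseases$dim == k) {
    dis <- diseases
  } else {
    dfit <- fit_pca_reduce(diseases, k)
    dis <- dfit$embedding
    dis_model <- dfit$pca_model
  }
  list(drugs = fit$embedding, diseases = dis,
       pca_model = fit$pca_model, pca_model_disease = dis_model)
}
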