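# Strict cold-start scoring: entities absent from the training graph are
# queried through their raw (pre-graph) embeddings only.

#' Find the most similar training entities in the original embedding space
#'
#' Exact top-k cosine retrieval against the training entities' raw
#' embeddings, independent of any learned association pattern. Ties are
#' broken by lower index, so results are deterministic.
#'
#' @param query numeric vector in the original feature space (nonzero norm).
#' @param training_raw an [embedding_matrix()] (or matrix) of training
#'   entities.
#' @param k number of neighbours, `1 <= k <= N`.
#' @return list with `neighbor_ids` (integer indices into `training_raw`),
#'   `neighbor_sims` (cosines, non-increasing).
#' @export
find_neighbors <- function(query, training_raw, k) {
  X <- if (inherits(training_raw, "embedding_matrix")) training_raw$matrix else training_raw
  if (k < 1 || k > nrow(X)) stopf("k must satisfy 1 <= k <= N_train")
  qn <- sqrt(sum(query^2))
  if (qn == 0) stopf("zero-norm query vector")
  rn <- sqrt(rowSums(X^2))
  if (any(rn == 0)) stopf("zero-norm training row %d", which(rn == 0)[1])
  sims <- drop(X %*% query) / (rn * qn)
  ord <- order(sims, decreasing = TRUE)[seq_len(k)]  # stable: ties -> lower index
  list(neighbor_ids = ord, neighbor_sims = sims[ord])
}

#' Temperature-scaled attention pseudo-query
#'
#' Aggregates the trained (fused) representations of the retrieved
#' neighbours with weights `Softmax(sims / temperature)`. Lower temperatures
#' sharpen the weights towards the nearest neighbour; the output always lies
#' in the convex hull of the neighbours' embeddings.
#'
#' @param neighbor_trained k x d matrix of the neighbours' trained
#'   embeddings (rows aligned with `neighbor_sims`).
#' @param neighbor_sims cosine similarities from [find_neighbors()].
#' @param temperature positive scalar (default 0.1).
#' @return numeric vector of length d.
#' @export
pseudo_query <- function(neighbor_trained, neighbor_sims, temperature = 0.1) {
  if (temperature <= 0) stopf("temperature must be positive")
  neighbor_trained <- as.matrix(neighbor_trained)
  if (nrow(neighbor_trained) != length(neighbor_sims))
    stopf("neighbour count mismatch")
  if (length(neighbor_sims) < 1) stopf("need at least one neighbour")
  l <- neighbor_sims / temperature
  w <- exp(l - max(l)); w <- w / sum(w)
  unname(drop(crossprod(neighbor_trained, w)))
}

#' Score an unseen entity against all candidate partners
#'
#' Scores the pseudo-query against each candidate with the trained decoder,
#' whose parameters are left untouched (asserted via hash).
#'
#' @param pseudo fused-space pseudo-embedding of the unseen entity.
#' @param candidates matrix of the other entity type's trained fused
#'   embeddings (one candidate per row).
#' @param model a `dream_model` (its decoder is used frozen).
#' @param entity_type `"drug"` if the unseen entity is a drug (so candidates
#'   are diseases), else `"disease"`.
#' @return numeric vector of probabilities, one per candidate.
#' @export
score_unseen <- function(pseudo, candidates, model, entity_type = c("drug", "disease")) {
  entity_type <- match.arg(entity_type)
  dec_names <- grep("^dec_", names(model$par), value = TRUE)
  if (!length(dec_names)) stopf("model has no trained decoder")
  hash_before <- sum(vapply(model$par[dec_names], function(p) sum(p^2), numeric(1)))
  k <- nrow(candidates)
  Q <- matrix(pseudo, k, length(pseudo), byrow = TRUE)
  s <- if (entity_type == "drug") score_pair(Q, candidates, model$par)
       else score_pair(candidates, Q, model$par)
  hash_after <- sum(vapply(model$par[dec_names], function(p) sum(p^2), numeric(1)))
  stopifnot(identical(hash_before, hash_after))
  s
}

#' Entity-wise cold-start cross-validation
#'
#' Splits drugs (or diseases) into `n_folds` groups; for each fold the
#' held-out entities are removed from the association matrix, the similarity
#' graphs and the feature harmonisation before training, so they are truly
#' unseen. Inference uses the trained model without retraining: raw-space
#' neighbour retrieval ([find_neighbors()]), a temperature-scaled
#' pseudo-query ([pseudo_query()]) in the fused embedding space, and the
#' frozen decoder ([score_unseen()]). Metrics cover all pairs between
#' held-out entities and trained partners.
#'
#' @inheritParams run_cv
#' @param mode `"unseen_drug"` or `"unseen_disease"`.
#' @return a `metrics_report` with per-fold AUROC/AUPRC.
#' @export
coldstart_cv <- function(assoc, drug_emb, disease_emb,
                         drug_sim = NULL, disease_sim = NULL,
                         cfg = dream_config(), mode = c("unseen_drug", "unseen_disease"),
                         n_folds = 10L, seed = 1L) {
  mode <- match.arg(mode)
  A <- assoc$matrix
  n_ent <- if (mode == "unseen_drug") nrow(A) else ncol(A)
  ent_folds <- withr::with_seed(seed, split(sample(n_ent),
                                            rep_len(seq_len(n_folds), n_ent)))
  res <- list()
  for (f in seq_len(n_folds)) {
    held <- sort(ent_folds[[f]])
    keep <- setdiff(seq_len(n_ent), held)
    if (mode == "unseen_drug") {
      sub_assoc <- association_table(A[keep, , drop = FALSE],
                                     assoc$drug_ids[keep], assoc$disease_ids)
      sub_demb <- embedding_matrix(drug_emb$matrix[keep, , drop = FALSE],
                                   drug_emb$entity_ids[keep], drug_emb$modality)
      sub_dsim <- if (!is.null(drug_sim))
        similarity_table(drug_sim$matrix[keep, keep, drop = FALSE],
                         drug_sim$entity_ids[keep]) else NULL
      inputs <- rebuild_fold_inputs(NULL, sub_assoc, sub_demb, disease_emb,
                                    sub_dsim, disease_sim, cfg)
    } else {
      sub_assoc <- association_table(A[, keep, drop = FALSE],
                                     assoc$drug_ids, assoc$disease_ids[keep])
      sub_memb <- embedding_matrix(disease_emb$matrix[keep, , drop = FALSE],
                                   disease_emb$entity_ids[keep], disease_emb$modality)
      sub_msim <- if (!is.null(disease_sim))
        similarity_table(disease_sim$matrix[keep, keep, drop = FALSE],
                         disease_sim$entity_ids[keep]) else NULL
      inputs <- rebuild_fold_inputs(NULL, sub_assoc, drug_emb, sub_memb,
                                    drug_sim, sub_msim, cfg)
    }
    model <- train_model(inputs, cfg, seed = derive_seed(seed, f))

    raw_train <- if (mode == "unseen_drug") drug_emb$matrix[keep, , drop = FALSE]
                 else disease_emb$matrix[keep, , drop = FALSE]
    raw_all <- if (mode == "unseen_drug") drug_emb$matrix else disease_emb$matrix
    n_d_sub <- inputs$dim[1]
    Z_ent <- if (mode == "unseen_drug") model$Z[seq_len(n_d_sub), , drop = FALSE]
             else model$Z[n_d_sub + seq_len(inputs$dim[2]), , drop = FALSE]
    Z_cand <- if (mode == "unseen_drug") model$Z[n_d_sub + seq_len(inputs$dim[2]), , drop = FALSE]
              else model$Z[seq_len(n_d_sub), , drop = FALSE]

    scores <- c(); ys <- c()
    kk <- min(cfg$coldstart$k, nrow(raw_train))
    for (e in held) {
      nb <- find_neighbors(raw_all[e, ], raw_train, kk)
      pq <- pseudo_query(Z_ent[nb$neighbor_ids, , drop = FALSE],
                         nb$neighbor_sims, cfg$coldstart$temperature)
      s <- score_unseen(pq, Z_cand, model,
                        if (mode == "unseen_drug") "drug" else "disease")
      yv <- if (mode == "unseen_drug") A[e, ] else A[, e]
      scores <- c(scores, s); ys <- c(ys, yv)
    }
    if (sum(ys == 1) == 0 || sum(ys == 0) == 0) {
      warnf("fold %d skipped: held-out entities have a single-class label set", f)
      next
    }
    res[[f]] <- data.frame(fold = f,
                           auroc = auroc(scores, ys), auprc = auprc(scores, ys),
                           n_test_pos = sum(ys == 1), n_test_unk = sum(ys == 0))
  }
  per_fold <- do.call(rbind, res)
  structure(list(per_fold = per_fold,
                 mean = list(auroc = mean(per_fold$auroc),
                             auprc = mean(per_fold$auprc)),
                 sd = list(auroc = stats::sd(per_fold$auroc),
                           auprc = stats::sd(per_fold$auprc)),
                 cfg = cfg, seed = seed, mode = mode,
                 held = lapply(unname(ent_folds), sort)),
            class = "metrics_report")
}
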