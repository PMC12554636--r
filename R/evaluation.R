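#' Build a 10-fold cross-validation plan over pairs
#'
#' Positives and unknown pairs are shuffled (seeded) and split independently
#' into `n_folds` near-equal parts (sizes differ by at most 1), so every
#' pair — positive or unknown — is tested exactly once and the full negative
#' set is used for evaluation without subsampling.
#'
#' @param assoc an [association_table()].
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return object of class `fold_plan`: list `folds` of length `n_folds`,
#'   each with `test_pos` and `test_unk` (linear indices into the
#'   drugs x diseases grid), plus `dim`, `seed`.
#' @export
make_folds <- function(assoc, n_folds = 10L, seed = 1L) {
  stopifnot(inherits(assoc, "association_table"))
  A <- assoc$matrix
  pos <- which(A == 1)
  unk <- which(A == 0)
  if (length(pos) < n_folds)
    stopf("fewer positives (%d) than folds (%d)", length(pos), n_folds)
  split_even <- function(x) {
    x <- sample(x)
    split(x, rep_len(seq_len(n_folds), length(x)))
  }
  withr::with_seed(seed, {
    ps <- split_even(pos)
    us <- split_even(unk)
    folds <- lapply(seq_len(n_folds), function(f)
      list(test_pos = sort(ps[[f]]), test_unk = sort(us[[f]])))
    structure(list(folds = folds, dim = dim(A), n_folds = n_folds, seed = seed),
              class = "fold_plan")
  })
}

#' Rebuild all training-time structures for one fold
#'
#' Leakage-free fold rebuild: the bipartite training graph contains only
#' training-fold positives, and the feature harmonisation (PCA) and the four
#' similarity graphs are computed without any test-pair labels (embeddings
#' and predefined similarities are label-free, so these are identical across
#' folds; they are still recomputed per fold). An internal audit asserts
#' that no test positive appears as a graph edge.
#'
#' @param fold one element of `fold_plan$folds` (or `NULL` to train on all
#'   pairs).
#' @param assoc an [association_table()].
#' @param drug_emb an [embedding_matrix()] of unified drug features (use
#'   [stack_drug_features()] first for multi-modality inputs).
#' @param disease_emb an [embedding_matrix()].
#' @param drug_sim,disease_sim optional predefined [similarity_table()]s;
#'   when absent the similarity route runs on the embedding-derived graph
#'   alone.
#' @param cfg a [dream_config()].
#' @return list of fold inputs consumed by [train_model()]: `Xd`, `Xm`
#'   (harmonised features), `Ahat` (normalised adjacencies of the similarity
#'   graphs), `graph_template`, `train_pos`, `train_unk_idx`, `test_pos`,
#'   `test_unk`, `pca_model`.
#' @export
rebuild_fold_inputs <- function(fold, assoc, drug_emb, disease_emb,
                                drug_sim = NULL, disease_sim = NULL,
                                cfg = dream_config()) {
  A <- assoc$matrix
  n_d <- nrow(A); n_m <- ncol(A)
  test_pos <- fold$test_pos %||% integer(0)
  test_unk <- fold$test_unk %||% integer(0)
  test_all <- c(test_pos, test_unk)
  train_mask <- matrix(TRUE, n_d, n_m)
  train_mask[test_all] <- FALSE

  harm <- harmonize_features(drug_emb, disease_emb, cfg$feat$n_components)

  train_pos_idx <- setdiff(which(A == 1), test_pos)
  train_unk_idx <- setdiff(which(A == 0), test_unk)
  train_pos <- arrayInd(train_pos_idx, dim(A))

  build_graphs <- function(emb, sim) {
    gs <- list()
    if (!is.null(sim))
      gs$pred <- knn_similarity_graph(sim, cfg$knn$k, "precomputed",
                                      symmetrize = cfg$knn$symmetrize,
                                      dense = cfg$knn$predefined_dense)
    gs$feat <- knn_similarity_graph(emb, cfg$knn$k, "cosine",
                                    symmetrize = cfg$knn$symmetrize)
    gs
  }
  gd <- build_graphs(harm$drugs, drug_sim)
  gm <- build_graphs(harm$diseases, disease_sim)

  graph_template <- structure(list(n_drugs = n_d, n_diseases = n_m,
                                   edges = data.frame()),
                              class = "bipartite_graph")

  inputs <- list(
    Xd = harm$drugs$matrix, Xm = harm$diseases$matrix,
    Ahat = list(drug = lapply(gd, normalize_adjacency),
                disease = lapply(gm, normalize_adjacency)),
    graph_template = graph_template,
    train_pos = train_pos, train_unk_idx = train_unk_idx,
    test_pos = test_pos, test_unk = test_unk,
    dim = dim(A), pca_model = harm$pca_model)
  audit_fold_leakage(inputs)
  inputs
}

#' Assert that no held-out pair can leak into training structures
#'
#' Checks that no test positive appears among the training-positive edges
#' and that the training and test index sets are disjoint. Called
#' automatically by [rebuild_fold_inputs()]; exported so cross-validation
#' drivers and tests can re-run the audit on every fold.
#'
#' @param inputs fold inputs from [rebuild_fold_inputs()].
#' @return `TRUE` invisibly; errors on any leakage.
#' @export
audit_fold_leakage <- function(inputs) {
  tp_lin <- (inputs$train_pos[, 2] - 1) * inputs$dim[1] + inputs$train_pos[, 1]
  if (length(intersect(tp_lin, c(inputs$test_pos, inputs$test_unk))))
    stopf("leakage: a held-out pair appears among training edges")
  if (length(intersect(inputs$test_pos, inputs$test_unk)))
    stopf("leakage: overlapping test positive/unknown sets")
  if (length(intersect(tp_lin, inputs$train_unk_idx)))
    stopf("inconsistent fold: pair marked both positive and unknown")
  if (length(intersect(inputs$train_unk_idx, inputs$test_unk)))
    stopf("leakage: held-out unknown available for negative sampling")
  invisible(TRUE)
}

#' Area under the ROC curve
#'
#' Probability that a uniformly chosen positive outranks a uniformly chosen
#' negative, with ties counted one half (midrank formulation).
#'
#' @param scores numeric predictions.
#' @param labels 0/1 vector; both classes must be present.
#' @return value in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stopf("both classes must be present")
  r <- rank(scores)   # midranks handle ties
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated area (average precision): precision at each distinct
#' score threshold weighted by the recall increment. Tied scores enter as a
#' single threshold.
#'
#' @inheritParams auroc
#' @return value in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  np <- sum(labels == 1)
  if (np == 0 || np == length(labels)) stopf("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' F1 score and recall at a fixed threshold
#'
#' Secondary metrics; the default threshold is 0.5.
#'
#' @inheritParams auroc
#' @param threshold classification cut-off on `scores`.
#' @return list with `f1`, `recall`, `precision`.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(f1 = f1, recall = rec, precision = prec)
}

#' Two-sided paired t-test on per-fold metrics
#'
#' @param values_a,values_b numeric vectors of equal length (>= 2), e.g.
#'   per-fold AUPRC of two methods.
#' @return list with `t` and `p`. Zero-variance differences warn and return
#'   the conventional degenerate result (`t = +/-Inf`, `p = 0` for a nonzero
#'   constant shift; `t = 0`, `p = 1` for identical vectors).
#' @export
paired_t_test <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stopf("unequal lengths")
  if (length(values_a) < 2) stopf("need at least 2 paired values")
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    warnf("zero-variance differences in paired t-test")
    if (mean(d) == 0) return(list(t = 0, p = 1))
    return(list(t = sign(mean(d)) * Inf, p = 0))
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Run leakage-free k-fold cross-validation
#'
#' For each fold: rebuild the training structures ([rebuild_fold_inputs()]),
#' train ([train_model()]), score every held-out pair — the fold's positives
#' plus all of its unknowns, with no negative subsampling — and compute
#' AUROC/AUPRC.
#'
#' @param assoc an [association_table()].
#' @param drug_emb,disease_emb [embedding_matrix()]s.
#' @param drug_sim,disease_sim optional predefined [similarity_table()]s.
#' @param cfg a [dream_config()].
#' @param n_folds number of folds (default 10).
#' @param seed integer seed (fold assignment and per-fold training).
#' @return object of class `metrics_report`: `per_fold` data.frame (fold,
#'   auroc, auprc, n_test_pos, n_test_unk), `mean` and `sd` lists, `cfg`,
#'   `seed`.
#' @export
run_cv <- function(assoc, drug_emb, disease_emb,
                   drug_sim = NULL, disease_sim = NULL,
                   cfg = dream_config(), n_folds = 10L, seed = 1L) {
  plan <- make_folds(assoc, n_folds, seed)
  res <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    inputs <- rebuild_fold_inputs(plan$folds[[f]], assoc, drug_emb, disease_emb,
                                  drug_sim, disease_sim, cfg)
    model <- train_model(inputs, cfg, seed = derive_seed(seed, f))
    test_idx <- c(inputs$test_pos, inputs$test_unk)
    pairs <- arrayInd(test_idx, inputs$dim)
    y <- rep(c(1, 0), c(length(inputs$test_pos), length(inputs$test_unk)))
    s <- predict_pairs(model, pairs)
    res[[f]] <- data.frame(fold = f, auroc = auroc(s, y), auprc = auprc(s, y),
                           n_test_pos = length(inputs$test_pos),
                           n_test_unk = length(inputs$test_unk))
  }
  per_fold <- do.call(rbind, res)
  structure(list(per_fold = per_fold,
                 mean = list(auroc = mean(per_fold$auroc),
                             auprc = mean(per_fold$auprc)),
                 sd = list(auroc = stats::sd(per_fold$auroc),
                           auprc = stats::sd(per_fold$auprc)),
                 cfg = cfg, seed = seed),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d folds: AUROC %.4f +/- %.4f, AUPRC %.4f +/- %.4f\n",
              nrow(x$per_fold), x$mean$auroc, x$sd$auroc, x$mean$auprc, x$sd$auprc))
  invisible(x)
}
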