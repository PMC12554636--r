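# End-to-end training of the dual-route model on one fold's inputs.

# Build the per-relation message matrices for a realised epoch graph
epoch_state <- function(inputs, cfg, pos_pairs, neg_idx, training) {
  g <- inputs$graph_template
  rc_pos <- pos_pairs
  rc_neg <- arrayInd(neg_idx, c(g$n_drugs, g$n_diseases))
  g$edges <- data.frame(
    drug = c(rc_pos[, 1], rc_neg[, 1]),
    disease = c(rc_pos[, 2], rc_neg[, 2]),
    relation = rep(c("known", "unknown"), c(nrow(rc_pos), nrow(rc_neg))),
    stringsAsFactors = FALSE)
  Xd <- inputs$Xd; Xm <- inputs$Xm
  if (training && cfg$aug$edge_dropout_p > 0)
    g <- edge_dropout(g, cfg$aug$edge_dropout_p)
  if (training && cfg$aug$feature_sigma > 0) {
    Xd <- gaussian_perturb(Xd, cfg$aug$feature_sigma)
    Xm <- gaussian_perturb(Xm, cfg$aug$feature_sigma)
  }
  list(Xd = Xd, Xm = Xm,
       M_list = relation_matrices(g, cfg$topo$share_direction_params),
       Ahat = inputs$Ahat)
}

#' Train the dual-route model on one fold's inputs
#'
#' Runs mini-batch-free full-graph training: each epoch resamples the
#' unknown-relation negatives (1:1 with training positives by default),
#' applies the augmentations (Gaussian feature perturbation, edge dropout),
#' runs the two encoders, fuses, scores the training positives plus the
#' sampled negatives, and takes one AdamW step on the binary cross-entropy.
#' Optionally holds out a slice of training positives for early stopping.
#' Fully deterministic given `seed`.
#'
#' @param inputs fold inputs from [rebuild_fold_inputs()].
#' @param cfg a [dream_config()].
#' @param seed integer seed controlling initialisation, sampling and
#'   augmentation.
#' @return object of class `dream_model`: trained parameters `par`, the
#'   configuration, `loss_trace`, the evaluation-mode fused embeddings `Z`
#'   (training entities, drugs first) and bookkeeping needed for scoring.
#' @export
train_model <- function(inputs, cfg, seed = 1L) {
  withr::with_seed(seed, {
    dims <- list(p = ncol(inputs$Xd),
                 n_drugs = nrow(inputs$Xd), n_diseases = nrow(inputs$Xm),
                 graphs_drug = names(inputs$Ahat$drug),
                 graphs_disease = names(inputs$Ahat$disease))
    par <- init_params(cfg, dims)
    opt <- adamw_init(par)

    pos <- inputs$train_pos          # matrix cols drug, disease
    unk <- inputs$train_unk_idx      # linear indices into the n_d x n_m grid
    n_pos <- nrow(pos)
    if (n_pos < 1) stopf("no training positives")

    val_pos <- NULL; val_neg <- NULL
    if (cfg$train$val_frac > 0 && n_pos >= 20) {
      nv <- max(1L, floor(cfg$train$val_frac * n_pos))
      vi <- sample(n_pos, nv)
      val_pos <- pos[vi, , drop = FALSE]
      pos <- pos[-vi, , drop = FALSE]
      vn <- sample(unk, min(length(unk), nv))
      val_neg <- arrayInd(vn, c(dims$n_drugs, dims$n_diseases))
      unk <- setdiff(unk, vn)
      n_pos <- nrow(pos)
    }
    n_neg <- min(length(unk), ceiling(cfg$train$neg_ratio * n_pos))
    if (n_neg < 1) stopf("no training unknowns to sample negatives from")

    trace <- numeric(0)
    best <- list(par = par, val = Inf, bad = 0L)
    for (epoch in seq_len(cfg$train$epochs)) {
      neg_idx <- sample(unk, n_neg)
      st <- epoch_state(inputs, cfg, pos, neg_idx, training = TRUE)
      cache <- encoder_forward(par, st, cfg, training = TRUE)
      pairs <- rbind(pos, arrayInd(neg_idx, c(dims$n_drugs, dims$n_diseases)))
      y <- rep(c(1, 0), c(n_pos, n_neg))
      dec <- pair_logits(par, cache$Z, dims$n_drugs, pairs)
      loss <- bce_loss(dec$logit, y, logits = TRUE)
      if (!is.finite(loss))
        stopf("training diverged at epoch %d (non-finite loss); try a lower learning rate", epoch)
      trace <- c(trace, loss)
      grads <- encoder_backward(par, st, cfg, cache, dec, pairs, y)
      upd <- adamw_step(par, grads, opt, cfg$train$lr, cfg$train$weight_decay)
      par <- upd$par; opt <- upd$state

      if (!is.null(val_pos) && epoch %% cfg$train$val_every == 0) {
        vst <- epoch_state(inputs, cfg, pos,
                           sample(unk, n_neg), training = FALSE)
        vc <- encoder_forward(par, vst, cfg, training = FALSE)
        vp <- rbind(val_pos, val_neg)
        vy <- rep(c(1, 0), c(nrow(val_pos), nrow(val_neg)))
        vl <- bce_loss(pair_logits(par, vc$Z, dims$n_drugs, vp)$logit, vy,
                       logits = TRUE)
        if (vl < best$val - 1e-6) {
          best <- list(par = par, val = vl, bad = 0L)
        } else {
          best$bad <- best$bad + 1L
          if (best$bad >= cfg$train$patience) break
        }
      }
    }
    if (!is.null(val_pos) && is.finite(best$val)) par <- best$par

    # deterministic evaluation graph: all training positives; unknown-relation
    # edges only if configured (default off, so inference never depends on an
    # arbitrary unknown-pair sample)
    eval_neg <- if (isTRUE(cfg$topo$eval_unknown_edges)) {
      withr::with_seed(derive_seed(seed, 0L),
                       sample(inputs$train_unk_idx,
                              min(length(inputs$train_unk_idx),
                                  nrow(inputs$train_pos))))
    } else integer(0)
    est <- epoch_state(inputs, cfg, inputs$train_pos, eval_neg, training = FALSE)
    ec <- encoder_forward(par, est, cfg, training = FALSE)

    structure(list(par = par, cfg = cfg, dims = dims, loss_trace = trace,
                   Z = ec$Z, Ztopo = ec$Ztopo, Zsim = ec$Zsim,
                   eval_neg = eval_neg, seed = seed),
              class = "dream_model")
  })
}

#' @export
print.dream_model <- function(x, ...) {
  cat(sprintf("<dream_model> route=%s, %d drugs + %d diseases, %d epochs, final loss %.4f\n",
              x$cfg$route, x$dims$n_drugs, x$dims$n_diseases,
              length(x$loss_trace), utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' Score drug-disease pairs with a trained model
#'
#' Evaluation-mode scoring (no dropout, no augmentation) of arbitrary
#' (drug index, disease index) pairs against the model's fused embeddings.
#'
#' @param model a `dream_model` from [train_model()].
#' @param pairs 2-column matrix of 1-based (drug, disease) indices.
#' @return numeric vector of probabilities.
#' @export
predict_pairs <- function(model, pairs) {
  pairs <- as.matrix(pairs)
  unname(drop(sigmoid(pair_logits(model$par, model$Z, model$dims$n_drugs, pairs)$logit)))
}
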