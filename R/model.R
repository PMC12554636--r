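# Model internals: parameter container, cached forward pass, analytic
# backward pass and the AdamW optimiser. The exported spec-level operations
# (topology_layer, gcn_layer, fuse_similarity, ...) define the semantics;
# the functions here re-express them with the caches backpropagation needs,
# and the test suite checks the two against each other and against
# finite-difference gradients.

topo_relation_names <- function(share_directions) {
  if (share_directions) c("known", "unknown")
  else c("known_to_drug", "known_to_disease",
         "unknown_to_drug", "unknown_to_disease")
}

# dims: list(p, n_drugs, n_diseases, graphs_drug, graphs_disease)
init_params <- function(cfg, dims) {
  par <- list()
  d <- cfg$topo$out
  if (cfg$route != "similarity_only") {
    L <- cfg$topo$layers; B <- cfg$topo$bases
    rels <- topo_relation_names(cfg$topo$share_direction_params)
    for (l in seq_len(L)) {
      d_in <- if (l == 1) dims$p else cfg$topo$hidden
      for (b in seq_len(B))
        par[[sprintf("topo_V_l%d_%d", l, b)]] <- glorot(d_in, cfg$topo$hidden)
      a <- matrix(stats::rnorm(length(rels) * B, sd = 1 / sqrt(B)),
                  length(rels), B, dimnames = list(rels, NULL))
      par[[sprintf("topo_a_l%d", l)]] <- a
    }
    par$topo_proj <- glorot(cfg$topo$hidden, d)
  }
  if (cfg$route != "topology_only") {
    for (ent in c("drug", "disease")) {
      gnames <- dims[[paste0("graphs_", ent)]]
      pnames <- if (cfg$sim$share_params) rep("shared", length(gnames)) else gnames
      for (pn in unique(pnames)) {
        par[[sprintf("sim_%s_%s_W1", ent, pn)]] <- glorot(dims$p, cfg$sim$hidden1)
        par[[sprintf("sim_%s_%s_b1", ent, pn)]] <- numeric(cfg$sim$hidden1)
        par[[sprintf("sim_%s_%s_W2", ent, pn)]] <- glorot(cfg$sim$hidden1, d)
        par[[sprintf("sim_%s_%s_b2", ent, pn)]] <- numeric(d)
      }
      par[[sprintf("fuse_W_%s", ent)]] <- glorot(length(gnames) * d, d)
      par[[sprintf("fuse_b_%s", ent)]] <- numeric(d)
    }
  }
  if (cfg$route == "dual") {
    a <- cfg$fuse$attn_hidden
    par$attn_W1 <- glorot(d, a)
    par$attn_w2 <- stats::runif(a, -sqrt(6 / (a + 1)), sqrt(6 / (a + 1)))
  }
  h <- cfg$dec$hidden
  par$dec_W1 <- glorot(2 * d, h[1])
  par$dec_b1 <- numeric(h[1])
  par$dec_W2 <- glorot(h[1], h[2])
  par$dec_b2 <- numeric(h[2])
  par$dec_w3 <- stats::runif(h[2], -sqrt(6 / (h[2] + 1)), sqrt(6 / (h[2] + 1)))
  par$dec_b3 <- 0
  par
}

sim_param_name <- function(ent, gname, cfg) {
  if (cfg$sim$share_params) sprintf("sim_%s_shared", ent) else sprintf("sim_%s_%s", ent, gname)
}

# Full encoder forward pass over all nodes.
# state: list(Xd, Xm, M_list (per-relation message matrices of the realised
# bipartite graph), Ahat = list(drug = list(...), disease = list(...)))
# Returns Z (n x d) plus caches for backward.
encoder_forward <- function(par, state, cfg, training = FALSE) {
  n_d <- nrow(state$Xd); n_m <- nrow(state$Xm)
  n <- n_d + n_m
  d <- cfg$topo$out
  cache <- list(n_d = n_d, n_m = n_m)

  Ztopo <- NULL
  if (cfg$route != "similarity_only") {
    H0 <- rbind(state$Xd, state$Xm)
    L <- cfg$topo$layers
    H_list <- vector("list", L + 1); H_list[[1]] <- H0
    P_list <- vector("list", L)
    S_list <- vector("list", L)   # per layer: per-relation M_r %*% H^(l-1)
    W_list <- vector("list", L)
    for (l in seq_len(L)) {
      W_l <- basis_compose(par[[sprintf("topo_a_l%d", l)]],
                           lapply(seq_len(cfg$topo$bases),
                                  function(b) par[[sprintf("topo_V_l%d_%d", l, b)]]))
      S_l <- lapply(state$M_list, function(M) M %*% H_list[[l]])
      P <- 0
      for (r in names(S_l)) P <- P + S_l[[r]] %*% W_l[[r]]
      H_list[[l + 1]] <- if (cfg$topo$activation == "relu") relu(P) else P
      P_list[[l]] <- P; S_list[[l]] <- S_l; W_list[[l]] <- W_l
    }
    Havg <- Reduce(`+`, H_list[-1]) / L
    Ztopo <- Havg %*% par$topo_proj
    cache$topo <- list(H_list = H_list, P_list = P_list, S_list = S_list,
                       W_list = W_list, Havg = Havg)
  }

  Zsim <- NULL
  if (cfg$route != "topology_only") {
    ent_out <- list()
    cache$sim <- list()
    for (ent in c("drug", "disease")) {
      X <- if (ent == "drug") state$Xd else state$Xm
      gnames <- names(state$Ahat[[ent]])
      h2s <- list(); gc_cache <- list()
      for (gname in gnames) {
        A <- state$Ahat[[ent]][[gname]]
        pn <- sim_param_name(ent, gname, cfg)
        AX <- A %*% X
        pre1 <- sweep(AX %*% par[[paste0(pn, "_W1")]], 2, par[[paste0(pn, "_b1")]], `+`)
        H1 <- relu(pre1)
        AH1 <- A %*% H1
        pre2 <- sweep(AH1 %*% par[[paste0(pn, "_W2")]], 2, par[[paste0(pn, "_b2")]], `+`)
        H2 <- relu(pre2)
        h2s[[gname]] <- H2
        gc_cache[[gname]] <- list(AX = AX, pre1 = pre1, AH1 = AH1, pre2 = pre2, A = A)
      }
      C <- do.call(cbind, h2s)
      prez <- sweep(C %*% par[[paste0("fuse_W_", ent)]], 2,
                    par[[paste0("fuse_b_", ent)]], `+`)
      zf <- relu(prez)
      mask_f <- if (training) dropout_mask(nrow(zf), ncol(zf), cfg$sim$dropout) else NULL
      ent_out[[ent]] <- apply_mask(zf, mask_f)
      cache$sim[[ent]] <- list(gc = gc_cache, C = C, prez = prez, mask_f = mask_f,
                               gnames = gnames)
    }
    Zsim <- rbind(ent_out$drug, ent_out$disease)
  }

  if (cfg$route == "dual") {
    T1 <- tanh(Ztopo %*% par$attn_W1)
    T2 <- tanh(Zsim %*% par$attn_W1)
    lmat <- cbind(T1 %*% par$attn_w2, T2 %*% par$attn_w2)
    mask_attn <- if (training) dropout_mask(n, 2, cfg$fuse$attn_dropout) else NULL
    lmat <- apply_mask(lmat, mask_attn)
    w <- softmax2(lmat)
    Zpre <- Ztopo * w[, 1] + Zsim * w[, 2]
    cache$attn <- list(T1 = T1, T2 = T2, w = w, mask_attn = mask_attn)
  } else if (cfg$route == "topology_only") {
    Zpre <- Ztopo
  } else {
    Zpre <- Zsim
  }
  mask_final <- if (training) dropout_mask(n, d, cfg$sim$dropout) else NULL
  cache$mask_final <- mask_final
  cache$Ztopo <- Ztopo; cache$Zsim <- Zsim
  cache$Z <- apply_mask(Zpre, mask_final)
  cache
}

# pairs: matrix/data.frame with columns drug, disease (1-based)
pair_logits <- function(par, Z, n_d, pairs) {
  Zp <- cbind(Z[pairs[, 1], , drop = FALSE],
              Z[n_d + pairs[, 2], , drop = FALSE])
  decoder_forward(Zp, par)
}

# Analytic gradients of mean BCE over `pairs` w.r.t. every parameter.
encoder_backward <- function(par, state, cfg, cache, dec, pairs, y) {
  genv <- new.env(parent = emptyenv())
  gadd <- function(nm, val) {
    assign(nm, if (exists(nm, envir = genv)) get(nm, envir = genv) + val else val,
           envir = genv)
  }
  n_d <- cache$n_d; n <- n_d + cache$n_m
  d <- cfg$topo$out
  m <- length(y)

  dlogit <- (sigmoid(dec$logit) - y) / m
  gadd("dec_b3", sum(dlogit))
  gadd("dec_w3", drop(crossprod(dec$r2, dlogit)))
  dm2 <- outer(dlogit, par$dec_w3) * (dec$m2 > 0)
  gadd("dec_W2", crossprod(dec$r1, dm2))
  gadd("dec_b2", colSums(dm2))
  dm1 <- (dm2 %*% t(par$dec_W2)) * (dec$m1 > 0)
  gadd("dec_W1", crossprod(dec$Zp, dm1))
  gadd("dec_b1", colSums(dm1))
  dZp <- dm1 %*% t(par$dec_W1)

  dZ <- matrix(0, n, d)
  idx <- c(pairs[, 1], n_d + pairs[, 2])
  contrib <- rbind(dZp[, seq_len(d), drop = FALSE],
                   dZp[, d + seq_len(d), drop = FALSE])
  agg <- rowsum(contrib, idx)
  dZ[as.integer(rownames(agg)), ] <- agg

  dZpre <- apply_mask(dZ, cache$mask_final)

  dZtopo <- NULL; dZsim <- NULL
  if (cfg$route == "dual") {
    at <- cache$attn
    w1 <- at$w[, 1]; w2v <- at$w[, 2]
    dZtopo <- dZpre * w1
    dZsim <- dZpre * w2v
    dw1 <- rowSums(dZpre * cache$Ztopo)
    dw2 <- rowSums(dZpre * cache$Zsim)
    dl1 <- w1 * w2v * (dw1 - dw2)
    dlm <- cbind(dl1, -dl1)
    dlm <- apply_mask(dlm, at$mask_attn)
    for (view in 1:2) {
      Tv <- if (view == 1) at$T1 else at$T2
      Zv <- if (view == 1) cache$Ztopo else cache$Zsim
      dlv <- dlm[, view]
      gadd("attn_w2", drop(crossprod(Tv, dlv)))
      dpre <- outer(dlv, par$attn_w2) * (1 - Tv^2)
      gadd("attn_W1", crossprod(Zv, dpre))
      dZv <- dpre %*% t(par$attn_W1)
      if (view == 1) dZtopo <- dZtopo + dZv else dZsim <- dZsim + dZv
    }
  } else if (cfg$route == "topology_only") {
    dZtopo <- dZpre
  } else {
    dZsim <- dZpre
  }

  if (!is.null(dZsim)) {
    for (ent in c("drug", "disease")) {
      sc <- cache$sim[[ent]]
      rows <- if (ent == "drug") seq_len(n_d) else n_d + seq_len(cache$n_m)
      dz <- apply_mask(dZsim[rows, , drop = FALSE], sc$mask_f)
      dprez <- dz * (sc$prez > 0)
      gadd(paste0("fuse_W_", ent), crossprod(sc$C, dprez))
      gadd(paste0("fuse_b_", ent), colSums(dprez))
      dC <- dprez %*% t(par[[paste0("fuse_W_", ent)]])
      for (gi in seq_along(sc$gnames)) {
        gname <- sc$gnames[gi]
        pn <- sim_param_name(ent, gname, cfg)
        gcch <- sc$gc[[gname]]
        dH2 <- dC[, (gi - 1) * d + seq_len(d), drop = FALSE]
        dpre2 <- dH2 * (gcch$pre2 > 0)
        gadd(paste0(pn, "_W2"), crossprod(gcch$AH1, dpre2))
        gadd(paste0(pn, "_b2"), colSums(dpre2))
        dH1 <- gcch$A %*% (dpre2 %*% t(par[[paste0(pn, "_W2")]]))
        dpre1 <- dH1 * (gcch$pre1 > 0)
        gadd(paste0(pn, "_W1"), crossprod(gcch$AX, dpre1))
        gadd(paste0(pn, "_b1"), colSums(dpre1))
      }
    }
  }

  if (!is.null(dZtopo)) {
    tc <- cache$topo
    L <- cfg$topo$layers; B <- cfg$topo$bases
    gadd("topo_proj", crossprod(tc$Havg, dZtopo))
    dHavg <- (dZtopo %*% t(par$topo_proj)) / L
    dH_next <- dHavg   # gradient flowing into H^(L)
    for (l in seq(L, 1)) {
      dP <- if (cfg$topo$activation == "relu") dH_next * (tc$P_list[[l]] > 0) else dH_next
      a_l <- par[[sprintf("topo_a_l%d", l)]]
      da <- a_l * 0
      dH_prev <- if (l > 1) dHavg else NULL
      for (r in rownames(a_l)) {
        dW_r <- crossprod(tc$S_list[[l]][[r]], dP)
        for (b in seq_len(B)) {
          gadd(sprintf("topo_V_l%d_%d", l, b), a_l[r, b] * dW_r)
          da[r, b] <- da[r, b] + sum(par[[sprintf("topo_V_l%d_%d", l, b)]] * dW_r)
        }
        if (l > 1) {
          W_r <- tc$W_list[[l]][[r]]
          dH_prev <- dH_prev + t(state$M_list[[r]]) %*% (dP %*% t(W_r))
        }
      }
      gadd(sprintf("topo_a_l%d", l), da)
      if (l > 1) dH_next <- dH_prev
    }
  }

  as.list(genv)
}

# ---- AdamW ---------------------------------------------------------------

adamw_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

is_bias_param <- function(nm) grepl("_b[0-9]?($|_)", nm)

adamw_step <- function(par, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && !is_bias_param(nm))
      step <- step + lr * weight_decay * par[[nm]]
    par[[nm]] <- par[[nm]] - step
  }
  list(par = par, state = state)
}
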