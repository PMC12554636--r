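# The analytic backward pass is the one component with no external
# reference implementation, so it is checked against central finite
# differences of the full forward pass, for each route/sharing variant.

grad_check <- function(cfg, n_entries = 3, tol = 1e-4, seed = 5) {
  setup <- tiny_training_setup(cfg, seed = seed)
  inputs <- setup$inputs
  dims <- list(p = ncol(inputs$Xd), n_drugs = nrow(inputs$Xd),
               n_diseases = nrow(inputs$Xm),
               graphs_drug = names(inputs$Ahat$drug),
               graphs_disease = names(inputs$Ahat$disease))
  withr::with_seed(seed, {
    par <- init_params(cfg, dims)
    # push all pre-activations off the ReLU kinks so central differences
    # see a locally smooth loss
    par <- lapply(par, function(p) p + rnorm(length(p), 0, 0.05))
    neg <- sample(inputs$train_unk_idx, nrow(inputs$train_pos))
  })
  st <- epoch_state(inputs, cfg, inputs$train_pos, neg, training = FALSE)
  pairs <- rbind(inputs$train_pos, arrayInd(neg, inputs$dim))
  y <- rep(c(1, 0), c(nrow(inputs$train_pos), length(neg)))
  lossfun <- function(p) {
    ca <- encoder_forward(p, st, cfg, training = FALSE)
    bce_loss(pair_logits(p, ca$Z, dims$n_drugs, pairs)$logit, y, logits = TRUE)
  }
  ca <- encoder_forward(par, st, cfg, training = FALSE)
  dec <- pair_logits(par, ca$Z, dims$n_drugs, pairs)
  gr <- encoder_backward(par, st, cfg, ca, dec, pairs, y)
  eps <- 1e-6
  for (nm in names(par)) {
    n_i <- min(length(par[[nm]]), n_entries)
    idx <- withr::with_seed(seed + 1, sample(length(par[[nm]]), n_i))
    for (i in idx) {
      p1 <- par; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- par; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
      ana <- if (is.null(gr[[nm]])) 0 else gr[[nm]][i]
      expect_equal(ana, num, tolerance = tol,
                   label = sprintf("analytic grad %s[%d]", nm, i))
    }
  }
}

test_that("analytic gradients match finite differences (dual route)", {
  grad_check(tiny_config(aug = list(edge_dropout_p = 0, feature_sigma = 0),
                         sim = list(dropout = 0), fuse = list(attn_dropout = 0)))
})

test_that("analytic gradients match finite differences (untied directions, shared GCNs)", {
  grad_check(tiny_config(aug = list(edge_dropout_p = 0, feature_sigma = 0),
                         sim = list(dropout = 0, share_params = TRUE),
                         fuse = list(attn_dropout = 0),
                         topo = list(layers = 2L, hidden = 6L, out = 4L,
                                     bases = 2L, share_direction_params = FALSE)))
})

test_that("analytic gradients match finite differences (single-route ablations)", {
  grad_check(tiny_config(route = "topology_only",
                         aug = list(edge_dropout_p = 0, feature_sigma = 0),
                         sim = list(dropout = 0)))
  grad_check(tiny_config(route = "similarity_only",
                         aug = list(edge_dropout_p = 0, feature_sigma = 0),
                         sim = list(dropout = 0)))
})

test_that("training is deterministic given a seed and reduces the loss", {
  setup <- tiny_training_setup()
  m1 <- train_model(setup$inputs, setup$cfg, seed = 11)
  m2 <- train_model(setup$inputs, setup$cfg, seed = 11)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$par, m2$par)

  # with augmentation disabled the trace is equally reproducible
  cfg0 <- tiny_config(aug = list(edge_dropout_p = 0, feature_sigma = 0))
  m3 <- train_model(setup$inputs, cfg0, seed = 12)
  m4 <- train_model(setup$inputs, cfg0, seed = 12)
  expect_identical(m3$loss_trace, m4$loss_trace)

  # optimisation sanity: a longer clean run drives the loss well down
  cfg_fit <- tiny_config(train = list(epochs = 80L),
                         aug = list(edge_dropout_p = 0, feature_sigma = 0))
  m5 <- train_model(setup$inputs, cfg_fit, seed = 13)
  expect_lt(mean(utils::tail(m5$loss_trace, 5)), m5$loss_trace[1] - 0.15)
})

test_that("AdamW step follows the update rule and decays weights only", {
  par <- list(W = matrix(c(1, -2), 1, 2), some_b1 = c(0.5))
  gr <- list(W = matrix(c(0.1, 0.2), 1, 2), some_b1 = c(-0.3))
  st <- adamw_init(par)
  out <- adamw_step(par, gr, st, lr = 0.1, weight_decay = 0.5)
  # first step: m_hat = g, v_hat = g^2  =>  step ~ lr * sign(g) (+ decay)
  expW <- par$W - 0.1 * (gr$W / (abs(gr$W) + 1e-8)) - 0.1 * 0.5 * par$W
  expb <- par$some_b1 - 0.1 * (gr$some_b1 / (abs(gr$some_b1) + 1e-8))
  expect_equal(out$par$W, expW, tolerance = 1e-6)
  expect_equal(out$par$some_b1, expb, tolerance = 1e-6)
})

test_that("fused embeddings feed a consistent pair scorer", {
  setup <- tiny_training_setup()
  m <- train_model(setup$inputs, setup$cfg, seed = 13)
  pairs <- rbind(c(1, 1), c(3, 2), c(5, 4))
  s <- predict_pairs(m, pairs)
  expect_length(s, 3)
  expect_true(all(s > 0 & s < 1))
  # agrees with score_pair on the stored fused embeddings
  manual <- score_pair(m$Z[pairs[, 1], ],
                       m$Z[m$dims$n_drugs + pairs[, 2], ], m$par)
  expect_equal(s, manual, tolerance = 1e-12)
})
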