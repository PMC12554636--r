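test_that("fold plans partition positives and unknowns independently", {
  dat <- synthetic_generate(tiny_spec(n_drugs = 15L, n_diseases = 10L,
                                      assoc_density = 0.18))
  plan <- make_folds(dat$assoc, 5, seed = 3)
  A <- dat$assoc$matrix
  all_pos <- sort(unlist(lapply(plan$folds, `[[`, "test_pos")))
  all_unk <- sort(unlist(lapply(plan$folds, `[[`, "test_unk")))
  expect_identical(all_pos, which(A == 1))
  expect_identical(all_unk, which(A == 0))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(plan$folds[[i]]$test_pos, plan$folds[[j]]$test_pos), 0)
    expect_length(intersect(plan$folds[[i]]$test_unk, plan$folds[[j]]$test_unk), 0)
  }
})

test_that("fold sizes differ by at most one (23 positives over 10 folds)", {
  withr::with_seed(4, {
    A <- matrix(0, 10, 10)
    A[sample(100, 23)] <- 1
  })
  plan <- make_folds(association_table(A), 10, seed = 1)
  sizes <- vapply(plan$folds, function(f) length(f$test_pos), integer(1))
  expect_equal(sum(sizes), 23L)
  expect_lte(max(sizes) - min(sizes), 1L)
  A2 <- matrix(0, 3, 3); A2[1:4] <- 1
  expect_error(make_folds(association_table(A2), 10), "fewer positives")
})

test_that("fold rebuilds are leakage-free and locally stable", {
  dat <- synthetic_generate(tiny_spec())
  cfg <- tiny_config()
  plan <- make_folds(dat$assoc, 4, seed = 2)
  inp1 <- rebuild_fold_inputs(plan$folds[[1]], dat$assoc, dat$drug_emb,
                              dat$disease_emb, dat$drug_sim, dat$disease_sim, cfg)
  expect_true(audit_fold_leakage(inp1))
  tp_lin <- (inp1$train_pos[, 2] - 1) * inp1$dim[1] + inp1$train_pos[, 1]
  expect_length(intersect(tp_lin, inp1$test_pos), 0)

  # similarity graphs are label-free, hence identical across folds
  inp2 <- rebuild_fold_inputs(plan$folds[[2]], dat$assoc, dat$drug_emb,
                              dat$disease_emb, dat$drug_sim, dat$disease_sim, cfg)
  expect_equal(inp1$Ahat, inp2$Ahat, tolerance = 1e-14)
  expect_equal(inp1$Xd, inp2$Xd, tolerance = 1e-14)

  # removing one training positive changes exactly one known edge
  drop_pair <- inp1$train_pos[1, ]
  A2 <- dat$assoc$matrix; A2[drop_pair[1], drop_pair[2]] <- 0
  inp3 <- rebuild_fold_inputs(plan$folds[[1]], association_table(A2),
                              dat$drug_emb, dat$disease_emb,
                              dat$drug_sim, dat$disease_sim, cfg)
  expect_equal(nrow(inp3$train_pos), nrow(inp1$train_pos) - 1L)
  lin1 <- (inp1$train_pos[, 2] - 1) * inp1$dim[1] + inp1$train_pos[, 1]
  lin3 <- (inp3$train_pos[, 2] - 1) * inp1$dim[1] + inp3$train_pos[, 1]
  expect_identical(sort(setdiff(lin1, lin3)),
                   (drop_pair[2] - 1) * inp1$dim[1] + drop_pair[1])
})

test_that("AUROC equals the pairwise-counting probability with tie handling", {
  expect_equal(auroc(c(.9, .8, .2, .1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(.1, .2, .8, .9), c(1, 1, 0, 0)), 0)
  withr::with_seed(6, {
    s <- sample(c(0.1, 0.35, 0.5, 0.5, 0.7, 0.9))  # includes a tie
    y <- c(1, 0, 1, 0, 0, 1)
    # brute-force count over all positive-negative pairs, ties half
    pos <- s[y == 1]; neg <- s[y == 0]
    cnt <- 0
    for (p in pos) for (n in neg) cnt <- cnt + (p > n) + 0.5 * (p == n)
    expect_equal(auroc(s, y), cnt / (length(pos) * length(neg)))
    # cross-check against an independent implementation
    skip_if_not_installed("pROC")
    s2 <- runif(60); y2 <- rbinom(60, 1, 0.4)
    expect_equal(auroc(s2, y2),
                 as.numeric(pROC::auc(pROC::roc(y2, s2, quiet = TRUE,
                                                levels = c(0, 1),
                                                direction = "<"))),
                 tolerance = 1e-10)
  })
  expect_error(auroc(c(.1, .2), c(1, 1)), "both classes")
})

test_that("AUPRC equals step-interpolated precision over recall increments", {
  expect_equal(auprc(c(.9, .8, .2), c(1, 1, 0)), 1)
  withr::with_seed(7, {
    s <- runif(40); y <- rbinom(40, 1, 0.3)
    # oracle: walk the ranked list threshold by threshold
    o <- order(s, decreasing = TRUE)
    ys <- y[o]; ss <- s[o]
    area <- 0; prev_rec <- 0; tp <- 0; fp <- 0; np <- sum(y)
    i <- 1
    while (i <= 40) {
      j <- i
      while (j < 40 && ss[j + 1] == ss[i]) j <- j + 1
      tp <- tp + sum(ys[i:j]); fp <- fp + sum(1 - ys[i:j])
      rec <- tp / np
      area <- area + (rec - prev_rec) * tp / (tp + fp)
      prev_rec <- rec
      i <- j + 1
    }
    expect_equal(auprc(s, y), area, tolerance = 1e-12)
  })
  expect_error(auprc(c(.1, .2), c(0, 0)), "both classes")
})

test_that("threshold metrics follow their definitions", {
  m <- threshold_metrics(c(.9, .6, .4, .2), c(1, 0, 1, 0), 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)
})

test_that("paired t-test matches the closed form and its conventions", {
  withr::with_seed(8, {
    b <- runif(10)
    a <- b + 0.05 + rnorm(10, 0, 0.01)
    res <- paired_t_test(a, b)
    d <- a - b
    t_exp <- mean(d) / (sd(d) / sqrt(10))
    expect_equal(res$t, t_exp, tolerance = 1e-12)
    expect_equal(res$p, 2 * pt(-abs(t_exp), 9), tolerance = 1e-12)
    # antisymmetry
    res2 <- paired_t_test(b, a)
    expect_equal(res2$t, -res$t, tolerance = 1e-12)
    expect_equal(res2$p, res$p, tolerance = 1e-12)
  })
  expect_warning(r0 <- paired_t_test(1:5, 1:5), "zero-variance")
  expect_equal(r0$t, 0)
  expect_warning(rc <- paired_t_test(1:5 + 1, 1:5), "zero-variance")
  expect_identical(rc$t, Inf)
  expect_equal(rc$p, 0)
})

test_that("cross-validation reports are internally consistent", {
  dat <- synthetic_generate(tiny_spec())
  cfg <- tiny_config(train = list(epochs = 8L))
  rep <- run_cv(dat$assoc, dat$drug_emb, dat$disease_emb,
                dat$drug_sim, dat$disease_sim, cfg, n_folds = 3, seed = 4)
  expect_equal(nrow(rep$per_fold), 3)
  expect_equal(rep$mean$auroc, mean(rep$per_fold$auroc))
  expect_equal(rep$mean$auprc, mean(rep$per_fold$auprc))
  expect_true(all(rep$per_fold$auroc >= 0 & rep$per_fold$auroc <= 1))
  # every pair tested exactly once across folds
  expect_equal(sum(rep$per_fold$n_test_pos) + sum(rep$per_fold$n_test_unk),
               length(dat$assoc$matrix))
})

test_that("the similarity route can run without predefined matrices", {
  dat <- synthetic_generate(tiny_spec())
  cfg <- tiny_config(train = list(epochs = 8L))
  rep <- run_cv(dat$assoc, dat$drug_emb, dat$disease_emb,
                NULL, NULL, cfg, n_folds = 2, seed = 5)
  expect_equal(nrow(rep$per_fold), 2)
  expect_true(all(is.finite(rep$per_fold$auprc)))
})
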