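test_that("masked mean pooling averages exactly the masked-in rows", {
  withr::with_seed(1, {
    states <- matrix(rnorm(40), 5, 8)
    mask <- c(1, 1, 0, 1, 0)
    expect_equal(masked_mean_pool(states, mask),
                 (states[1, ] + states[2, ] + states[4, ]) / 3)
    # single selected row comes back verbatim
    expect_equal(masked_mean_pool(states, c(0, 0, 1, 0, 0)), states[3, ])
    # permutation invariance over masked-in rows
    perm <- c(4, 1, 3, 2, 5)
    expect_equal(masked_mean_pool(states[perm, ], mask[perm]),
                 masked_mean_pool(states, mask))
  })
  expect_error(masked_mean_pool(matrix(1, 2, 2), c(0, 0)), "no tokens")
})

test_that("zero padding preserves values and row norms", {
  e <- rand_emb(4, 6, seed = 2)
  p <- zero_pad(e, 10)
  expect_equal(p$dim, 10)
  expect_equal(p$matrix[, 1:6], e$matrix, ignore_attr = TRUE)
  expect_true(all(p$matrix[, 7:10] == 0))
  expect_equal(sqrt(rowSums(p$matrix^2)), sqrt(rowSums(e$matrix^2)),
               ignore_attr = TRUE)
  expect_identical(zero_pad(e, 6), e)
  expect_error(zero_pad(e, 5), "target_dim")
})

test_that("stacking drug modalities pads, orders, and detects conflicts", {
  sm <- rand_emb(3, 4, seed = 3, modality = "small_molecule")
  pr <- embedding_matrix(matrix(rnorm(6), 1, 6), "p1", "protein")
  ord <- c("p1", "e02", "e01", "e03")
  st <- stack_drug_features(sm, pr, ord)
  expect_equal(dim(st$matrix), c(4L, 6L))
  expect_equal(st$matrix["p1", ], pr$matrix[1, ], ignore_attr = TRUE)
  expect_equal(st$matrix["e02", ], c(sm$matrix["e02", ], 0, 0), ignore_attr = TRUE)

  smonly <- stack_drug_features(sm, NULL, c("e03", "e01", "e02"))
  expect_equal(smonly$matrix, sm$matrix[c("e03", "e01", "e02"), ],
               ignore_attr = TRUE)
  dup <- embedding_matrix(matrix(1, 1, 6), "e01", "protein")
  expect_error(stack_drug_features(sm, dup, ord), "more than one source")
  expect_error(stack_drug_features(sm, pr, c(ord, "ghost")), "missing")
})

test_that("PCA projection matches an independent SVD oracle", {
  withr::with_seed(7, {
    X <- matrix(rnorm(60), 10, 6)
    emb <- embedding_matrix(X)
    fit <- fit_pca_reduce(emb, 3)
    # oracle: full SVD computed independently, same sign convention applied
    Xc <- scale(X, scale = FALSE)
    V <- svd(Xc)$v[, 1:3]
    for (j in 1:3) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
    expect_equal(fit$embedding$matrix, Xc %*% V, ignore_attr = TRUE,
                 tolerance = 1e-10)
    expect_true(all(diff(fit$pca_model$explained_variance) <= 1e-12))
    # components orthonormal
    G <- crossprod(fit$pca_model$components)
    expect_equal(G, diag(3), tolerance = 1e-10)
    # projecting the training rows reproduces the scores
    expect_equal(project_pca(X, fit$pca_model), fit$embedding$matrix,
                 ignore_attr = TRUE, tolerance = 1e-12)
  })
})

test_that("PCA edge cases: rank-1 input, clamping, padded coordinates", {
  u <- 1:6
  X <- outer(c(1, 3, 5, 7), u / sqrt(sum(u^2)))
  fit <- fit_pca_reduce(embedding_matrix(X), 2)
  ev <- fit$pca_model$explained_variance
  expect_gt(ev[1] / sum(ev), 1 - 1e-10)

  expect_warning(fit_pca_reduce(rand_emb(5, 3), 10), "clamped")

  # zero-padded coordinates get zero loadings: no information invented
  e <- rand_emb(8, 4, seed = 9)
  pad <- zero_pad(e, 7)
  fpad <- fit_pca_reduce(pad, 3)
  expect_true(all(abs(fpad$pca_model$components[5:7, ]) < 1e-12))
})

test_that("PCA reconstruction beats random rank-n projections", {
  withr::with_seed(11, {
    X <- matrix(rnorm(200), 20, 10)
    Xc <- scale(X, scale = FALSE)
    fit <- fit_pca_reduce(embedding_matrix(X), 3)
    V <- fit$pca_model$components
    err_pca <- sum((Xc - Xc %*% V %*% t(V))^2)
    for (i in 1:10) {
      Q <- qr.Q(qr(matrix(rnorm(30), 10, 3)))
      expect_lte(err_pca, sum((Xc - Xc %*% Q %*% t(Q))^2) + 1e-9)
    }
  })
})

test_that("harmonisation yields equal drug/disease widths", {
  drugs <- rand_emb(15, 10, seed = 4)
  dis_match <- rand_emb(8, 6, seed = 5)
  h <- harmonize_features(drugs, dis_match, 6)
  expect_equal(ncol(h$drugs$matrix), 6)
  expect_identical(h$diseases, dis_match)   # passthrough when widths match
  expect_null(h$pca_model_disease)

  dis_other <- rand_emb(8, 9, seed = 6)
  h2 <- harmonize_features(drugs, dis_other, 6)
  expect_equal(ncol(h2$drugs$matrix), ncol(h2$diseases$matrix))
  expect_false(is.null(h2$pca_model_disease))
})
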