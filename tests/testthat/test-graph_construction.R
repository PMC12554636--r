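test_that("bipartite graph keeps training positives and samples unknowns", {
  a <- association_table(matrix(c(1, 0, 0, 0), 2, 2))
  g <- build_bipartite_graph(a, unknown_sample_size = 1, rng_seed = 3)
  expect_equal(sum(g$edges$relation == "known"), 1)
  expect_equal(sum(g$edges$relation == "unknown"), 1)
  unk <- g$edges[g$edges$relation == "unknown", ]
  lin <- (unk$disease - 1) * 2 + unk$drug
  expect_true(lin %in% which(a$matrix == 0))   # among the 3 unknown pairs

  g0 <- build_bipartite_graph(a, unknown_sample_size = 0)
  expect_equal(nrow(g0$edges), 1)
  expect_error(build_bipartite_graph(a, unknown_sample_size = 10), "exceeds")
})

test_that("held-out pairs can never become edges", {
  dat <- synthetic_generate(tiny_spec())
  A <- dat$assoc$matrix
  mask <- matrix(TRUE, nrow(A), ncol(A))
  test_idx <- which(A == 1)[1:3]
  mask[test_idx] <- FALSE
  g <- build_bipartite_graph(dat$assoc, mask, unknown_sample_size = 5, rng_seed = 1)
  lin <- (g$edges$disease - 1) * nrow(A) + g$edges$drug
  expect_length(intersect(lin, test_idx), 0)
})

test_that("kNN graph matches an exhaustive-sort oracle and keeps raw weights", {
  withr::with_seed(13, {
    X <- rbind(matrix(rnorm(3 * 4, mean = 3), 3, 4),
               matrix(rnorm(3 * 4, mean = -3), 3, 4))
    emb <- embedding_matrix(X)
    g <- knn_similarity_graph(emb, k = 2)
    Xn <- X / sqrt(rowSums(X^2))
    S <- pmax(Xn %*% t(Xn), 0); diag(S) <- 0
    sel <- matrix(FALSE, 6, 6)
    for (i in 1:6) sel[i, order(S[i, ], decreasing = TRUE)[1:2]] <- TRUE
    keep <- sel | t(sel)
    expect_equal(g$weights, S * keep, ignore_attr = TRUE, tolerance = 1e-12)
    # weights are the raw similarity values, not binarised
    nz <- g$weights[g$weights > 0]
    expect_true(all(abs(nz - S[g$weights > 0]) < 1e-12))
  })
})

test_that("kNN graph edge cases: complete graph, mutual mode, zero rows", {
  e <- rand_emb(5, 3, seed = 21)
  gc <- knn_similarity_graph(e, k = 4)          # k = N-1: complete
  offdiag <- gc$weights[upper.tri(gc$weights)]
  Xn <- e$matrix / sqrt(rowSums(e$matrix^2))
  S <- pmax(Xn %*% t(Xn), 0)
  expect_equal(offdiag, S[upper.tri(S)], ignore_attr = TRUE)

  gu <- knn_similarity_graph(e, k = 1, symmetrize = "union")
  gm <- knn_similarity_graph(e, k = 1, symmetrize = "mutual")
  expect_true(all(gm$weights <= gu$weights + 1e-15))

  bad <- embedding_matrix(rbind(c(1, 0), c(0, 0)))
  expect_error(knn_similarity_graph(bad, k = 1), "zero-norm")
  expect_error(knn_similarity_graph(e, k = 5), "k must")

  st <- similarity_table((diag(4) + 1) / 2)
  gp <- knn_similarity_graph(st, k = 2)
  expect_equal(gp$source, "predefined")
})

test_that("symmetric normalisation matches closed forms and the direct formula", {
  expect_equal(normalize_adjacency(matrix(0, 3, 3)), diag(3))
  expect_equal(normalize_adjacency(matrix(c(0, 1, 1, 0), 2, 2)),
               matrix(0.5, 2, 2))
  # weighted triangle: element-wise brute force
  A <- matrix(c(0, .5, .2,
                .5, 0, .7,
                .2, .7, 0), 3, 3)
  Ahat <- normalize_adjacency(A)
  Ai <- A + diag(3)
  D <- rowSums(Ai)
  for (i in 1:3) for (j in 1:3)
    expect_equal(Ahat[i, j], Ai[i, j] / sqrt(D[i] * D[j]), tolerance = 1e-12)
})

test_that("normalised adjacency has spectral radius at most 1", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      n <- sample(3:8, 1)
      A <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) > 0.5)
      A <- (A + t(A)) / 2; diag(A) <- 0
      ev <- eigen(normalize_adjacency(A), symmetric = TRUE, only.values = TRUE)$values
      expect_lte(max(abs(ev)), 1 + 1e-10)
    }
  })
})

test_that("edge dropout removes the right fraction and respects limits", {
  a <- association_table(matrix(1, 100, 100))
  g <- build_bipartite_graph(a, unknown_sample_size = 0)
  expect_equal(nrow(edge_dropout(g, 0)$edges), 10000)
  expect_equal(nrow(edge_dropout(g, 1)$edges), 0)
  kept <- nrow(edge_dropout(g, 0.10, rng_seed = 7)$edges) / 10000
  se <- sqrt(0.9 * 0.1 / 10000)
  expect_lt(abs(kept - 0.9), 3 * se)
  expect_error(edge_dropout(g, 1.5), "\\[0, 1\\]")

  sg <- knn_similarity_graph(rand_emb(10, 4, seed = 1), k = 3)
  sgd <- edge_dropout(sg, 0.5, rng_seed = 2)
  expect_identical(sgd$weights, t(sgd$weights))
  expect_lte(sum(sgd$weights > 0), sum(sg$weights > 0))
})

test_that("gaussian perturbation has the right moments and determinism", {
  X <- matrix(0, 200, 200)
  expect_identical(gaussian_perturb(X, 0), X)
  Y <- gaussian_perturb(X, 0.05, rng_seed = 5)
  expect_lt(abs(sd(Y - X) - 0.05) / 0.05, 0.02)
  expect_identical(Y, gaussian_perturb(X, 0.05, rng_seed = 5))
  expect_error(gaussian_perturb(X, -1), "non-negative")
})
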