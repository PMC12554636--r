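# Shared fixtures: everything is generated in code at test time.

tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(n_drugs = 12L, n_diseases = 9L, n_blocks = 3L, embed_dim = 6L,
         assoc_density = 0.2, protein_frac = 0.25, opaque_frac = 0.2,
         seed = 42L),
    list(...))
  do.call(synthetic_spec, args)
}

# small but fully wired configuration for fast training tests; overrides
# given by the caller win over the tiny defaults, group-wise
tiny_config <- function(...) {
  base <- list(feat = list(n_components = 4L),
               knn = list(k = 2L),
               topo = list(layers = 2L, hidden = 6L, out = 4L, bases = 2L),
               sim = list(hidden1 = 5L, hidden2 = 4L),
               fuse = list(attn_hidden = 3L),
               dec = list(hidden = c(6L, 4L)),
               train = list(epochs = 30L))
  over <- list(...)
  for (nm in names(over)) {
    base[[nm]] <- if (nm %in% names(base) && is.list(base[[nm]]))
      utils::modifyList(base[[nm]], over[[nm]]) else over[[nm]]
  }
  do.call(dream_config, c(list(preset = "desk"), base))
}

rand_emb <- function(n, d, seed = 1, modality = "synthetic") {
  withr::with_seed(seed,
    embedding_matrix(matrix(rnorm(n * d), n, d),
                     sprintf("e%02d", seq_len(n)), modality))
}

# fold inputs + initial params for gradient/consistency tests
tiny_training_setup <- function(cfg = tiny_config(), seed = 5) {
  dat <- synthetic_generate(tiny_spec(seed = seed))
  inputs <- suppressWarnings(
    rebuild_fold_inputs(NULL, dat$assoc, dat$drug_emb, dat$disease_emb,
                        dat$drug_sim, dat$disease_sim, cfg))
  list(dat = dat, inputs = inputs, cfg = cfg)
}

# independent naive implementation of the relational message-passing layer:
# explicit loops over nodes, relations and neighbours (oracle for Eq-style
# aggregation; deliberately slow and simple)
naive_topology_layer <- function(h, g, weights, activation = "relu") {
  n <- g$n_drugs + g$n_diseases
  out <- matrix(0, n, ncol(weights[[1]]))
  e <- g$edges
  nodes_of <- function(rel) {
    er <- e[e$relation == rel, , drop = FALSE]
    cbind(er$drug, g$n_drugs + er$disease)
  }
  for (rel in unique(e$relation)) {
    pe <- nodes_of(rel)
    deg <- tabulate(c(pe[, 1], pe[, 2]), nbins = n)
    for (v in seq_len(n)) {
      nb <- c(pe[pe[, 1] == v, 2], pe[pe[, 2] == v, 1])
      for (u in nb) {
        coef <- 1 / sqrt(deg[u] * deg[v])
        out[v, ] <- out[v, ] + coef * drop(h[u, ] %*% weights[[rel]])
      }
    }
  }
  if (activation == "relu") pmax(out, 0) else out
}
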