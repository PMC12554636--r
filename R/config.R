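#' Model and training configuration
#'
#' Builds the nested configuration list consumed by [train_model()],
#' [run_cv()] and [coldstart_cv()]. Defaults are the grid-search optima of
#' the published benchmark study (layer counts, widths, k, dropout rates,
#' learning rate, weight decay); the `"desk"` preset scales widths and epochs
#' down so a full cross-validation runs in seconds on the bundled synthetic
#' data while exercising exactly the same code paths.
#'
#' @param preset `"benchmark"` (full-size defaults) or `"desk"`
#'   (small-width configuration used throughout the test suite).
#' @param ... named overrides for any top-level group, e.g.
#'   `topo = list(layers = 2)`; entries are merged over the preset.
#' @return a named list with groups `feat`, `knn`, `topo`, `sim`, `fuse`,
#'   `dec`, `train`, `aug`, `coldstart` and scalar `route`.
#'
#' @details Groups and keys:
#' \describe{
#'   \item{feat}{`n_components` (PCA target dimension for the unified drug
#'     matrix, default 768, clamped to `min(N, D)` with a warning on small
#'     data), `pca_per_fold` (fit the PCA on training entities only).}
#'   \item{knn}{`k` neighbours (default 4), `symmetrize` (`"union"` or
#'     `"mutual"`), `predefined_dense` (skip top-k sparsification of
#'     predefined similarity graphs).}
#'   \item{topo}{`layers` (default 3), `hidden` aggregation width (1024),
#'     `out` output width (128), `bases` basis count B (4), `activation`
#'     (`"relu"` or `"identity"`), `share_direction_params` (one weight
#'     matrix per relation used in both edge directions; `FALSE` is the
#'     parameter-sharing ablation), `eval_unknown_edges` (whether the
#'     evaluation-time graph carries a fixed sample of unknown-relation
#'     edges; default `FALSE` so test-time representations never depend on
#'     an arbitrary resample).}
#'   \item{sim}{`hidden1` (768), `hidden2` (128, must equal `topo$out`),
#'     `dropout` (0.3, also used for the post-fusion dropout),
#'     `share_params` (tie the two graph convolutions of one entity type).}
#'   \item{fuse}{`attn_hidden` (attention bottleneck, 64), `attn_dropout`
#'     (0.1, applied to the per-view attention logits; 0 disables).}
#'   \item{dec}{`hidden` integer vector of the two decoder hidden widths,
#'     default `c(256, 64)`.}
#'   \item{train}{`lr` (2e-3), `weight_decay` (1e-5), `epochs` (1000),
#'     `patience` (early-stopping patience in validation checks, 50),
#'     `val_frac` (fraction of training positives held out for early
#'     stopping, 0.05), `val_every` (epochs between checks, 10),
#'     `neg_ratio` (sampled unknowns per training positive, 1).}
#'   \item{aug}{`edge_dropout_p` (0.10), `feature_sigma` (0.05); set both to
#'     0 for the no-augmentation ablation.}
#'   \item{coldstart}{`k` retrieval neighbours (4), `temperature` (0.1).}
#'   \item{route}{`"dual"`, `"topology_only"` or `"similarity_only"`.}
#' }
#' @examples
#' cfg <- dream_config("desk", train = list(epochs = 50))
#' cfg$topo$layers
#' @export
dream_config <- function(preset = c("benchmark", "desk"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    feat = list(n_components = 768L, pca_per_fold = TRUE),
    knn = list(k = 4L, symmetrize = "union", predefined_dense = FALSE),
    topo = list(layers = 3L, hidden = 1024L, out = 128L, bases = 4L,
                activation = "relu", share_direction_params = TRUE,
                eval_unknown_edges = FALSE),
    sim = list(hidden1 = 768L, hidden2 = 128L, dropout = 0.3,
               share_params = FALSE),
    fuse = list(attn_hidden = 64L, attn_dropout = 0.1),
    dec = list(hidden = c(256L, 64L)),
    train = list(lr = 2e-3, weight_decay = 1e-5, epochs = 1000L,
                 patience = 50L, val_frac = 0.05, val_every = 10L,
                 neg_ratio = 1),
    aug = list(edge_dropout_p = 0.10, feature_sigma = 0.05),
    coldstart = list(k = 4L, temperature = 0.1),
    route = "dual"
  )
  if (preset == "desk") {
    cfg$feat$n_components <- 24L
    cfg$topo$hidden <- 32L
    cfg$topo$out <- 16L
    cfg$sim$hidden1 <- 32L
    cfg$sim$hidden2 <- 16L
    cfg$fuse$attn_hidden <- 16L
    cfg$dec$hidden <- c(32L, 16L)
    cfg$train$lr <- 1e-2
    cfg$train$epochs <- 150L
    cfg$train$val_frac <- 0
  }
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stopf("unknown config group '%s'", nm)
    if (is.list(cfg[[nm]])) {
      bad <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
      if (length(bad)) stopf("unknown config key '%s$%s'", nm, bad[1])
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  stopifnot(cfg$route %in% c("dual", "topology_only", "similarity_only"))
  if (cfg$sim$hidden2 != cfg$topo$out) {
    stopf("sim$hidden2 (%d) must equal topo$out (%d): the two routes are fused in a common dimension",
          cfg$sim$hidden2, cfg$topo$out)
  }
  cfg
}
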