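#' @title Desk-scale experiment harness
#' @description Scripted reproductions of the method's internal studies on
#'   synthetic fixtures: the receptive-field sweep against a GCN baseline
#'   (over-smoothing), the graph-modality ablation, and the operator-sharing
#'   ablation. All variants within one comparison share the fixture, masks
#'   and seeds; inputs are fingerprinted so this can be asserted.
#' @name experiments
NULL

new_sweep_result <- function(axis, values, per_seed, extra = list()) {
  per_seed <- as.matrix(per_seed)
  structure(c(list(axis = axis, values = values, metric = "rmse",
                   mean = rowMeans(per_seed),
                   sd = if (ncol(per_seed) > 1)
                     apply(per_seed, 1, stats::sd)
                   else rep(0, nrow(per_seed)),
                   per_seed = per_seed, n_seeds = ncol(per_seed)),
              extra),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep_result over", x$axis, sprintf("(%d seeds):\n", x$n_seeds))
  for (i in seq_along(x$values))
    cat(sprintf("  %-12s RMSE %.4f +/- %.4f\n", x$values[i], x$mean[i],
                x$sd[i]))
  invisible(x)
}

# fixture -> normalized data + masks + graphs; the fixture's data seed is
# fixed so that only masks/init/walks vary across replicate seeds
prepare_run <- function(fixture = "layered", seed = 1L, data_seed = 11L,
                        n_hvg = 100, knn_k = 10) {
  sim <- make_fixture(fixture, seed = data_seed)
  norm <- normalize_counts(sim$dataset)
  split <- make_masks(norm, seed = seed)
  hvg <- select_hvg(norm, n_hvg = min(n_hvg, ncol(norm$values)))
  obs <- apply_mask(norm, split)
  hetero <- build_hetero_graph(obs, hvg = hvg, knn_k = knn_k)
  fp <- list(data = sum(norm$values@x),
             masks = sum(split$test_idx) + 31 * sum(split$val_idx))
  list(data = norm, split = split, hetero = hetero, fingerprint = fp,
       sim = sim)
}

# experiment-scale training defaults (small widths, capped epochs); the
# methods vignette documents these as the package's desk-scale choices
exp_train_config <- function(seed, max_epochs = 300, patience = 40,
                             lr = 1e-2) {
  train_config(max_epochs = max_epochs, patience = patience, lr = lr,
               weight_decay = 1e-5, seed = seed)
}

exp_model_config <- function(L = 2, d_emb = 16, k = 4, T = 2, ...) {
  model_config(L = L, d_emb = d_emb, k_s = k, k_g = k, T_s = T, T_g = T, ...)
}

run_path_model <- function(prep, mcfg, tcfg) {
  fit <- train_model(prep$data, prep$split, prep$hetero, mcfg, tcfg)
  X_obs <- apply_mask(prep$data, prep$split)$values
  X_hat <- impute(fit$model, X_obs, prep$hetero, seed = tcfg$seed)
  list(metrics = evaluate_imputation(X_hat, prep$data, prep$split),
       fit = fit, X_hat = X_hat)
}

#' Receptive-field sweep: path model vs GCN
#'
#' Trains both models at matched receptive fields on the same fixture,
#' masks and seeds. For the GCN the receptive field R is its depth; for the
#' path model R = (k - 1) * L with L fixed at 2 and walk length k = R/2 + 1
#' (fields must be even), so depth stays constant while reach varies.
#'
#' @param fixture fixture name (see [make_fixture]).
#' @param fields integer receptive fields, default `c(2, 8, 32)`.
#' @param models subset of `c("pathgnn", "gcn")`.
#' @param seeds replicate seeds (masks + init + walks), default `1:5`.
#' @param d_emb,T,epochs desk-scale model/training sizes.
#' @return named list of `sweep_result`s (one per model), each with
#'   per-field test RMSE, plus input `fingerprint`s.
#' @export
receptive_field_sweep <- function(fixture = "layered", fields = c(2, 8, 32),
                                  models = c("pathgnn", "gcn"), seeds = 1:5,
                                  d_emb = 16, T = 4, epochs = 300) {
  stopifnot(all(fields >= 1))
  out <- list()
  fps <- list()
  for (mdl in models) {
    per <- matrix(NA_real_, length(fields), length(seeds),
                  dimnames = list(as.character(fields), NULL))
    for (si in seq_along(seeds)) {
      prep <- prepare_run(fixture, seed = seeds[si])
      fps[[si]] <- prep$fingerprint
      for (fi in seq_along(fields)) {
        R <- fields[fi]
        tcfg <- exp_train_config(seeds[si], max_epochs = epochs)
        if (mdl == "gcn") {
          res <- baseline_gcn(prep$data, prep$split, prep$hetero,
                              depth = R, d_emb = d_emb, tcfg = tcfg)
          met <- evaluate_imputation(res$X_hat, prep$data, prep$split)
        } else {
          mcfg <- exp_model_config(L = 2, d_emb = d_emb,
                                   k = max(2L, as.integer(R / 2 + 1)), T = T)
          met <- run_path_model(prep, mcfg, tcfg)$metrics
        }
        per[fi, si] <- met$rmse
      }
    }
    out[[mdl]] <- new_sweep_result("receptive_field", fields, per,
                                   list(fingerprints = fps))
  }
  out
}

#' Graph-modality ablation
#'
#' Trains three variants on identical fixtures, masks and seeds: `var_s`
#' (spatial graph only — the layer combine consumes the spatial convolution
#' twice), `var_g` (gene-similarity graph only), and `var_h` (both).
#'
#' @param fixture fixture name.
#' @param seeds replicate seeds, default `1:5`.
#' @param mcfg base [model_config] (modality is overridden per variant).
#' @param epochs training epoch cap.
#' @return named list of three `sweep_result`s (`var_s`, `var_g`, `var_h`).
#' @export
modality_ablation <- function(fixture = "layered", seeds = 1:5,
                              mcfg = exp_model_config(), epochs = 300) {
  variants <- c(var_s = "spatial", var_g = "gene", var_h = "both")
  per <- matrix(NA_real_, 3, length(seeds),
                dimnames = list(names(variants), NULL))
  fps <- list()
  for (si in seq_along(seeds)) {
    prep <- prepare_run(fixture, seed = seeds[si])
    fps[[si]] <- prep$fingerprint
    for (v in names(variants)) {
      mc <- mcfg; mc$modality <- variants[[v]]
      tcfg <- exp_train_config(seeds[si], max_epochs = epochs)
      per[v, si] <- run_path_model(prep, mc, tcfg)$metrics$rmse
    }
  }
  lapply(stats::setNames(names(variants), names(variants)), function(v)
    new_sweep_result("modality", variants[[v]], per[v, , drop = FALSE],
                     list(fingerprints = fps)))
}

#' Operator-sharing ablation
#'
#' Trains the four operator-sharing variants under an identical protocol
#' and reports the per-mode test RMSE distribution and exact parameter
#' counts.
#'
#' @param fixture fixture name.
#' @param modes subset of `c("op_glo", "op_cha", "op_lay", "op_ind")`.
#' @param seeds replicate seeds, default `1:5`.
#' @param mcfg base [model_config] (share mode overridden per variant).
#' @param epochs training epoch cap.
#' @return a `sweep_result` over modes with `param_counts` attached.
#' @export
operator_ablation <- function(fixture = "layered", modes = SHARE_MODES,
                              seeds = 1:5, mcfg = exp_model_config(),
                              epochs = 300) {
  modes <- match.arg(modes, SHARE_MODES, several.ok = TRUE)
  per <- matrix(NA_real_, length(modes), length(seeds),
                dimnames = list(modes, NULL))
  fps <- list()
  m_genes <- NULL
  for (si in seq_along(seeds)) {
    prep <- prepare_run(fixture, seed = seeds[si])
    fps[[si]] <- prep$fingerprint
    m_genes <- ncol(prep$data$values)
    for (md in modes) {
      mc <- mcfg; mc$share_mode <- md
      tcfg <- exp_train_config(seeds[si], max_epochs = epochs)
      per[md, si] <- run_path_model(prep, mc, tcfg)$metrics$rmse
    }
  }
  counts <- vapply(modes, function(md) {
    mc <- mcfg; mc$share_mode <- md
    count_parameters(mc, m_genes)$operators
  }, numeric(1))
  new_sweep_result("share_mode", modes, per,
                   list(param_counts = counts, fingerprints = fps))
}

#' Embedding dispersion (over-smoothing diagnostic)
#'
#' Scale-invariant spread of node embeddings: mean per-dimension variance
#' across nodes divided by the mean squared magnitude. Over-smoothed
#' embeddings (all nodes alike) drive this toward zero.
#'
#' @param E `n x d` embedding matrix.
#' @return scalar dispersion.
#' @export
embedding_dispersion <- function(E) {
  E <- as.matrix(E)
  mean(apply(E, 2, stats::var)) / (mean(E^2) + 1e-12)
}
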