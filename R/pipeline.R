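#' Run the full imputation pipeline
#'
#' Load (or simulate) → normalize → mask → build graphs → train → impute →
#' evaluate, persisting every intermediate artifact plus a manifest
#' (resolved config, input checksums, seed, output paths) to `out_dir`.
#'
#' @param counts path to a counts file (mtx/csv/h5ad), or `NULL` to
#'   simulate.
#' @param coords path to a coordinate CSV/TSV (required with `counts`).
#' @param config a configuration tree from [resolve_config] (or a YAML
#'   path).
#' @param out_dir output directory, created if needed.
#' @param sim a [sim_config] used when `counts` is `NULL` (default: the
#'   layered fixture configuration).
#' @return the run manifest (named list), invisibly; `metrics.json` in
#'   `out_dir` holds the test-mask metric report.
#' @export
run_pipeline <- function(counts = NULL, coords = NULL,
                         config = resolve_config(), out_dir, sim = NULL) {
  if (is.character(config)) config <- resolve_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "load"
  inputs <- character(0)
  tryCatch({
    if (is.null(counts)) {
      stage <- "simulate"
      simres <- if (is.null(sim)) make_fixture("layered", seed = config$seed)
                else simulate_spatial(sim)
      dataset <- simres$dataset
      write_simulation(simres, file.path(out_dir, "simulated"))
    } else {
      stage <- "read_counts"
      dataset <- read_counts(counts, transpose = config$data$transpose)
      inputs <- c(inputs, counts)
      stage <- "read_coords"
      if (is.null(coords)) stop("coords file required with counts input")
      dataset$coords <- read_coords(coords, cell_ids = dataset$cell_ids)
      inputs <- c(inputs, coords)
      dataset <- filter_dataset(dataset, config$data$min_cells_per_gene,
                                config$data$min_genes_per_cell)
    }
    stage <- "normalize"
    norm <- normalize_counts(dataset, scheme = config$data$scheme,
                             scale_factor = config$data$scale_factor)
    stage <- "make_masks"
    split <- make_masks(norm, config$data$test_frac, config$data$val_frac,
                        seed = config$seed)
    write_masks(split, file.path(out_dir, "masks.json"))
    stage <- "graphs"
    obs <- apply_mask(norm, split)
    hvg <- select_hvg(norm, n_hvg = min(config$data$n_hvg, ncol(norm$values)))
    hetero <- build_hetero_graph(obs, hvg = hvg, d_thr = config$graph$d_thr,
                                 knn_k = config$graph$gene_knn)
    write_graph(hetero, file.path(out_dir, "graph.tsv"))
    stage <- "train"
    fit <- train_model(norm, split, hetero, config_model(config),
                       config_train(config))
    save_model(fit$model, file.path(out_dir, "model.json"))
    jsonlite::write_json(unclass(fit$report),
                         file.path(out_dir, "train_report.json"),
                         auto_unbox = TRUE, digits = NA)
    stage <- "evaluate"
    X_hat <- impute(fit$model, obs$values, hetero, seed = config$seed)
    Matrix::writeMM(Matrix::Matrix(X_hat, sparse = TRUE),
                    file.path(out_dir, "imputed.mtx"))
    metrics <- evaluate_imputation(X_hat, norm, split)
    jsonlite::write_json(unclass(metrics), file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    stage <- "manifest"
    manifest <- list(
      config = config,
      seed = config$seed,
      inputs = as.list(stats::setNames(
        as.character(tools::md5sum(inputs)), inputs)),
      outputs = list.files(out_dir, recursive = TRUE),
      versions = list(package = as.character(utils::packageVersion("pathimpute")),
                      R = R.version.string),
      metrics = unclass(metrics))
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Filter low-coverage genes and cells
#'
#' Config-driven thresholds: keep genes observed in at least
#' `min_cells_per_gene` cells and cells with at least `min_genes_per_cell`
#' observed genes (gene filter first).
#'
#' @param data an [expr_dataset].
#' @param min_cells_per_gene,min_genes_per_cell integer thresholds.
#' @return the filtered [expr_dataset].
#' @export
filter_dataset <- function(data, min_cells_per_gene = 1,
                           min_genes_per_cell = 1) {
  keep_g <- Matrix::colSums(data$values != 0) >= min_cells_per_gene
  v <- data$values[, keep_g, drop = FALSE]
  keep_c <- Matrix::rowSums(v != 0) >= min_genes_per_cell
  expr_dataset(v[keep_c, , drop = FALSE],
               cell_ids = data$cell_ids[keep_c],
               gene_ids = data$gene_ids[keep_g],
               coords = if (!is.null(data$coords))
                 data$coords[keep_c, , drop = FALSE],
               layer_labels = if (!is.null(data$layer_labels))
                 data$layer_labels[keep_c])
}

#' Save / load a trained model as JSON
#'
#' The checkpoint embeds the model configuration, so [load_model] restores
#' a forward-pass-identical model.
#'
#' @param model a `path_gnn`.
#' @param path JSON path.
#' @return `path` (save) or the restored `path_gnn` (load).
#' @export
save_model <- function(model, path) {
  ser <- list(config = unclass(model$config), m = model$m, d = model$d,
              n_slots = model$n_slots,
              params = lapply(model$params, function(x)
                if (is.matrix(x)) list(dim = dim(x), x = as.numeric(x))
                else list(dim = NULL, x = as.numeric(x))))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, ser$config[setdiff(names(ser$config), NULL)])
  params <- lapply(ser$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2) matrix(p$x, p$dim[1], p$dim[2])
    else as.numeric(p$x)
  })
  structure(list(config = cfg, m = as.integer(ser$m), d = as.integer(ser$d),
                 params = params, n_slots = as.integer(ser$n_slots)),
            class = "path_gnn")
}
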