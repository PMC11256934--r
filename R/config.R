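#' Default configuration tree
#'
#' Nested defaults for the full pipeline. Model and walk defaults mirror the
#' reference hyper-parameters (L = 4, d_emb = 64, path length 8, 8 walks per
#' node, q = 1, patience 50); data defaults use the dominant normalization
#' convention (library-size 1e4 + log1p) and the 10%/10% test/validation
#' masking of nonzero entries.
#'
#' @return nested named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    data = list(scheme = "lognorm", scale_factor = 1e4, n_hvg = 3100,
                test_frac = 0.10, val_frac = 0.10, transpose = FALSE,
                min_cells_per_gene = 1, min_genes_per_cell = 1),
    graph = list(d_thr = NULL, gene_knn = 6, target_degree = 6),
    model = list(L = 4, d_emb = 64, path_len_spatial = 8, path_len_gene = 8,
                 n_walks_spatial = 8, n_walks_gene = 8, q_s = 1, q_g = 1,
                 p = 1, share_mode = "op_ind", modality = "both",
                 raw_features = FALSE),
    train = list(max_epochs = 1000, patience = 50, lr = 1e-3,
                 weight_decay = 1e-5),
    seed = 1L
  )
}

#' Resolve a configuration
#'
#' Precedence: package defaults, then the YAML file, then `key=value`
#' overrides (dotted paths, e.g. `model.d_emb=32`). Unknown keys are
#' rejected with the nearest valid key named; type mismatches are rejected.
#'
#' @param file optional YAML file path.
#' @param overrides character vector of `section.key=value` strings.
#' @return the validated configuration tree.
#' @export
resolve_config <- function(file = NULL, overrides = character()) {
  cfg <- default_config()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    user <- yaml::read_yaml(file)
    if (length(user) > 0) {
      for (sec in names(user)) {
        if (sec == "seed") { cfg$seed <- check_type("seed", cfg$seed, user$seed); next }
        check_key(sec, names(cfg))
        for (key in names(user[[sec]])) {
          check_key(paste(sec, key, sep = "."),
                    paste(sec, names(cfg[[sec]]), sep = "."))
          cfg[[sec]][[key]] <- check_type(paste(sec, key, sep = "."),
                                          cfg[[sec]][[key]],
                                          user[[sec]][[key]])
        }
      }
    }
  }
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("override must be key=value, got '", ov, "'")
    path <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    val <- utils::type.convert(kv[2], as.is = TRUE)
    if (length(path) == 1 && path == "seed") {
      cfg$seed <- check_type("seed", cfg$seed, val)
    } else {
      if (length(path) != 2) stop("override key must be section.key: ", kv[1])
      check_key(path[1], names(cfg))
      check_key(kv[1], paste(path[1], names(cfg[[path[1]]]), sep = "."))
      cfg[[path[1]]][[path[2]]] <- check_type(kv[1], cfg[[path[1]]][[path[2]]],
                                              val)
    }
  }
  validate_config(cfg)
  cfg
}

check_key <- function(key, valid) {
  if (key %in% valid) return(invisible(key))
  near <- valid[which.min(utils::adist(key, valid))]
  stop("unknown config key '", key, "'; did you mean '", near, "'?")
}

check_type <- function(key, default, value) {
  if (is.null(default)) return(value)  # NULL defaults accept any scalar
  if (is.numeric(default) && !is.numeric(value))
    stop("config key '", key, "' expects a number, got '", value, "'")
  if (is.logical(default) && !is.logical(value))
    stop("config key '", key, "' expects TRUE/FALSE, got '", value, "'")
  if (is.character(default) && !is.character(value))
    stop("config key '", key, "' expects a string, got '", value, "'")
  value
}

validate_config <- function(cfg) {
  with(cfg$model, {
    if (!share_mode %in% SHARE_MODES)
      stop("model.share_mode must be one of ",
           paste(SHARE_MODES, collapse = ", "))
    if (!modality %in% c("both", "spatial", "gene"))
      stop("model.modality must be both/spatial/gene")
    stopifnot(L >= 1, d_emb >= 1, q_s > 0, q_g > 0, p > 0)
  })
  if (cfg$data$test_frac + cfg$data$val_frac >= 1)
    stop("data.test_frac + data.val_frac must be < 1")
  invisible(cfg)
}

config_model <- function(cfg) {
  model_config(L = cfg$model$L, d_emb = cfg$model$d_emb,
               k_s = cfg$model$path_len_spatial,
               k_g = cfg$model$path_len_gene,
               T_s = cfg$model$n_walks_spatial,
               T_g = cfg$model$n_walks_gene,
               q_s = cfg$model$q_s, q_g = cfg$model$q_g, p = cfg$model$p,
               share_mode = cfg$model$share_mode,
               modality = cfg$model$modality,
               raw_features = cfg$model$raw_features)
}

config_train <- function(cfg) {
  train_config(max_epochs = cfg$train$max_epochs,
               patience = cfg$train$patience, lr = cfg$train$lr,
               weight_decay = cfg$train$weight_decay, seed = cfg$seed)
}
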