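#' @title Path operators
#' @description A path operator is a learnable weight array with one weight
#'   per walk position (channel-shared modes: a length-`k` vector broadcast
#'   across embedding channels) or one weight per position and channel
#'   (channel-distinct modes: a `k x d` matrix). Convolving node embeddings
#'   along sampled walks with these weights replaces Laplacian neighborhood
#'   averaging and lets a single layer reach `k - 1` hops.
#'
#' Sharing modes across an `L`-layer model:
#' \describe{
#'   \item{op_glo}{one `k`-vector shared by all layers and channels}
#'   \item{op_cha}{per-layer `k`-vectors, channels shared}
#'   \item{op_lay}{one `k x d` matrix shared by all layers}
#'   \item{op_ind}{per-layer `k x d` matrices}
#' }
#' @name path_operator
NULL

SHARE_MODES <- c("op_glo", "op_cha", "op_lay", "op_ind")

share_channel_shared <- function(mode) mode %in% c("op_glo", "op_cha")
share_layer_shared <- function(mode) mode %in% c("op_glo", "op_lay")

#' Construct a path operator
#'
#' @param weights numeric length-`k` vector (channel-shared) or `k x d`
#'   matrix (channel-distinct).
#' @param graph_kind `"spatial"` or `"gene"`.
#' @param share_mode one of `"op_glo"`, `"op_cha"`, `"op_lay"`, `"op_ind"`.
#' @return an object of class `path_operator`.
#' @export
path_operator <- function(weights, graph_kind = "spatial",
                          share_mode = "op_ind") {
  share_mode <- match.arg(share_mode, SHARE_MODES)
  if (share_channel_shared(share_mode)) {
    weights <- as.numeric(weights)
  } else {
    weights <- as.matrix(weights)
  }
  structure(list(weights = weights, graph_kind = graph_kind,
                 share_mode = share_mode),
            class = "path_operator")
}

# dense k x d view of the operator weights
op_weight_matrix <- function(op, d) {
  w <- op$weights
  if (is.matrix(w)) {
    if (ncol(w) != d) stop("operator has ", ncol(w),
                           " channels, embeddings have ", d)
    w
  } else matrix(w, length(w), d)
}

#' Convolve node embeddings along sampled walks
#'
#' For each start node v the output is the average over its `T` walks of
#' the per-channel weighted sum of the visited nodes' embeddings:
#' `out(v)[j] = (1/T) * sum_walks sum_{i=1..k} op[i, j] * f(P_i)[j]`.
#' Position 1 of every walk is the start node itself, so each node always
#' contributes its own embedding.
#'
#' @param op a [path_operator] (or a bare `k`-vector / `k x d` matrix).
#' @param walks a [sample_walks] result with `walks$k` equal to the operator
#'   path length.
#' @param f numeric `n x d` node-embedding matrix.
#' @return numeric `n x d` matrix of convolved embeddings.
#' @export
path_convolve <- function(op, walks, f) {
  if (!inherits(op, "path_operator"))
    op <- path_operator(op, walks$graph_kind,
                        if (is.matrix(op)) "op_ind" else "op_cha")
  f <- as.matrix(f)
  d <- ncol(f)
  W <- op_weight_matrix(op, d)
  if (nrow(W) != walks$k)
    stop("operator path length ", nrow(W), ", walks have k = ", walks$k)
  wm <- walks$walks
  nT <- nrow(wm)
  acc <- matrix(0, nT, d)
  for (i in seq_len(walks$k))
    acc <- acc + f[wm[, i], , drop = FALSE] *
      matrix(W[i, ], nT, d, byrow = TRUE)
  n <- nT / walks$T
  # rows are grouped by start node (T consecutive): fold and average
  out <- colSums(array(acc, c(walks$T, n, d)), dims = 1) / walks$T
  matrix(out, n, d)
}

# backward of path_convolve: upstream gradient G (n x d) ->
# list(d_op (k x d, or k-vector if channel-shared), d_f (n x d))
path_convolve_backward <- function(op, walks, f, G) {
  d <- ncol(f)
  W <- op_weight_matrix(op, d)
  wm <- walks$walks
  nT <- nrow(wm)
  Gw <- G[walks$start_of, , drop = FALSE] / walks$T
  d_op <- matrix(0, walks$k, d)
  d_f <- matrix(0, nrow(f), d)
  for (i in seq_len(walks$k)) {
    fi <- f[wm[, i], , drop = FALSE]
    d_op[i, ] <- colSums(Gw * fi)
    contrib <- Gw * matrix(W[i, ], nT, d, byrow = TRUE)
    agg <- rowsum(contrib, group = wm[, i])
    rows <- as.integer(rownames(agg))
    d_f[rows, ] <- d_f[rows, , drop = FALSE] + agg
  }
  if (share_channel_shared(op$share_mode)) d_op <- rowSums(d_op)
  list(d_op = d_op, d_f = d_f)
}

#' One heterogeneous path-GNN layer
#'
#' Convolves the embeddings along spatial and gene walks, concatenates the
#' two results, and applies an affine map followed by ReLU:
#' `f_out = relu(W1 [conv_s, conv_g] + b)`.
#'
#' @param layer list with `op_s`, `op_g` ([path_operator]s), `W1`
#'   (`2*d_in x d_out`), `b` (length `d_out`).
#' @param walks_s,walks_g walk sets on the spatial and gene graphs.
#' @param f `n x d_in` input embeddings.
#' @param modality `"both"` (default), `"spatial"` (gene branch replaced by a
#'   duplicate of the spatial convolution) or `"gene"` (mirror image).
#' @return `n x d_out` matrix of nonnegative activations.
#' @export
layer_forward <- function(layer, walks_s, walks_g, f, modality = "both") {
  conv_s <- if (modality != "gene") path_convolve(layer$op_s, walks_s, f)
  conv_g <- if (modality != "spatial") path_convolve(layer$op_g, walks_g, f)
  if (modality == "spatial") conv_g <- conv_s
  if (modality == "gene") conv_s <- conv_g
  h <- cbind(conv_s, conv_g)
  z <- h %*% layer$W1 + matrix(layer$b, nrow(h), length(layer$b), byrow = TRUE)
  z * (z > 0)
}

#' Model configuration defaults
#'
#' Defaults mirror the reference hyper-parameters: 4 layers, embedding width
#' 64, walk node-length 8 (7 hops) with 8 walks per node on each graph,
#' in-out bias q = 1 and return bias p = 1, independent per-layer
#' per-channel operators.
#'
#' @param L layers; @param d_emb embedding width; @param k_s,k_g walk
#'   node-lengths; @param T_s,T_g walks per node; @param q_s,q_g,p walk
#'   biases; @param share_mode operator sharing mode; @param modality graph
#'   modality (`"both"`, `"spatial"`, `"gene"`); @param raw_features use
#'   `f(0) = X_obs` directly (no encoder/decoder, width `m`).
#' @return a `model_config` list.
#' @export
model_config <- function(L = 4, d_emb = 64, k_s = 8, k_g = 8, T_s = 8,
                         T_g = 8, q_s = 1, q_g = 1, p = 1,
                         share_mode = "op_ind", modality = "both",
                         raw_features = FALSE) {
  share_mode <- match.arg(share_mode, SHARE_MODES)
  modality <- match.arg(modality, c("both", "spatial", "gene"))
  stopifnot(L >= 1, d_emb >= 1, k_s >= 1, k_g >= 1, T_s >= 1, T_g >= 1,
            q_s > 0, q_g > 0, p > 0)
  structure(list(L = as.integer(L), d_emb = as.integer(d_emb),
                 k_s = as.integer(k_s), k_g = as.integer(k_g),
                 T_s = as.integer(T_s), T_g = as.integer(T_g),
                 q_s = q_s, q_g = q_g, p = p, share_mode = share_mode,
                 modality = modality, raw_features = raw_features),
            class = "model_config")
}

# operators start from a normalized geometrically decaying position profile
# (jittered), so the initial convolution approximates a *local* neighborhood
# mean regardless of path length; a flat 1/k start makes long paths begin as
# near-global averages with no usable signal
init_op_weights <- function(k, d, channel_shared, decay = 0.7) {
  w <- decay^(seq_len(k) - 1)
  w <- w / sum(w)
  if (channel_shared) w * stats::runif(k, 0.5, 1.5)
  else matrix(w, k, d) * matrix(stats::runif(k * d, 0.5, 1.5), k, d)
}

init_dense <- function(n_in, n_out) {
  r <- sqrt(6 / n_in)
  matrix(stats::runif(n_in * n_out, -r, r), n_in, n_out)
}

#' Initialize a path-GNN model
#'
#' @param config a [model_config].
#' @param m number of genes (output dimension).
#' @param seed integer seed for weight initialization.
#' @return an object of class `path_gnn`: list with `config`, `m`, and
#'   `params` (named list of numeric arrays). Operator slots are physically
#'   shared according to `share_mode`: layer-shared modes hold a single slot
#'   used by every layer.
#' @export
init_model <- function(config, m, seed = 1L) {
  stopifnot(inherits(config, "model_config"), m >= 1)
  d <- if (config$raw_features) as.integer(m) else config$d_emb
  cs <- share_channel_shared(config$share_mode)
  n_slots <- if (share_layer_shared(config$share_mode)) 1L else config$L
  params <- list()
  with_seed(seed, {
    if (!config$raw_features) {
      params$enc_W <- init_dense(m, d)
      params$enc_b <- numeric(d)
    }
    for (s in seq_len(n_slots)) {
      params[[paste0("op_s_", s)]] <- init_op_weights(config$k_s, d, cs)
      params[[paste0("op_g_", s)]] <- init_op_weights(config$k_g, d, cs)
    }
    for (l in seq_len(config$L)) {
      params[[paste0("W1_", l)]] <- init_dense(2 * d, d)
      params[[paste0("b_", l)]] <- numeric(d)
    }
    if (!config$raw_features) {
      params$dec_W1 <- init_dense(d, d)
      params$dec_b1 <- numeric(d)
      # near-zero output layer: the network's structural signal starts
      # silent (but alive), so it grows only where it reduces the loss
      # instead of fighting the output-bias solution at initialization
      params$dec_W2 <- init_dense(d, m) * 0.05
      params$dec_b2 <- numeric(m)
    }
  })
  structure(list(config = config, m = as.integer(m), d = d, params = params,
                 n_slots = n_slots),
            class = "path_gnn")
}

op_slot <- function(model, l) if (model$n_slots == 1L) 1L else l

model_operator <- function(model, l, kind) {
  w <- model$params[[paste0("op_", if (kind == "spatial") "s" else "g", "_",
                            op_slot(model, l))]]
  path_operator(w, kind, model$config$share_mode)
}

model_layer <- function(model, l) {
  list(op_s = model_operator(model, l, "spatial"),
       op_g = model_operator(model, l, "gene"),
       W1 = model$params[[paste0("W1_", l)]],
       b = model$params[[paste0("b_", l)]])
}

#' @export
print.path_gnn <- function(x, ...) {
  pc <- count_parameters(x$config, x$m)
  cat(sprintf(
    "path_gnn: L=%d, d_emb=%d, k=(%d,%d), T=(%d,%d), mode=%s, %d genes\n",
    x$config$L, x$d, x$config$k_s, x$config$k_g, x$config$T_s, x$config$T_g,
    x$config$share_mode, x$m))
  cat(sprintf("  parameters: %d (operators %d, combine %d, en/decoder %d)\n",
              pc$total, pc$operators, pc$combine, pc$encoder + pc$decoder))
  invisible(x)
}

#' Full model forward pass
#'
#' Encodes the observed matrix, applies `L` path-GNN layers with the given
#' walk sets, and decodes back to gene space, yielding the imputed matrix.
#'
#' @param model a [init_model] result.
#' @param X_obs `n x m` observed (masked) expression matrix, dense or sparse.
#' @param walks_s,walks_g walk sets on the spatial and gene graphs.
#' @return `n x m` imputed matrix. Deterministic given the walk sets.
#' @export
model_forward <- function(model, X_obs, walks_s, walks_g) {
  model_forward_cache(model, X_obs, walks_s, walks_g, keep = FALSE)$X_hat
}

# forward pass retaining intermediates for backprop when keep = TRUE
model_forward_cache <- function(model, X_obs, walks_s, walks_g, keep = TRUE) {
  cfg <- model$config
  if (inherits(X_obs, "sparseMatrix")) {
    if (length(X_obs@x) && any(!is.finite(X_obs@x)))
      stop("non-finite values in X_obs")
  } else if (any(!is.finite(X_obs))) stop("non-finite values in X_obs")
  if (ncol(X_obs) != model$m)
    stop("model built for ", model$m, " genes, input has ", ncol(X_obs))
  n <- nrow(X_obs)
  p <- model$params
  f <- if (cfg$raw_features) as.matrix(X_obs)
       else as.matrix(X_obs %*% p$enc_W) +
            matrix(p$enc_b, n, model$d, byrow = TRUE)
  fs <- list(f)
  convs <- list()
  for (l in seq_len(cfg$L)) {
    layer <- model_layer(model, l)
    cs <- if (cfg$modality != "gene") path_convolve(layer$op_s, walks_s, f)
    cg <- if (cfg$modality != "spatial") path_convolve(layer$op_g, walks_g, f)
    if (cfg$modality == "spatial") cg <- cs
    if (cfg$modality == "gene") cs <- cg
    h <- cbind(cs, cg)
    z <- h %*% layer$W1 + matrix(layer$b, n, length(layer$b), byrow = TRUE)
    f <- z * (z > 0)
    if (keep) { convs[[l]] <- list(h = h, z = z); fs[[l + 1]] <- f }
  }
  if (cfg$raw_features) {
    out <- list(X_hat = f)
    if (keep) out <- c(out, list(fs = fs, convs = convs))
    return(out)
  }
  zd <- f %*% p$dec_W1 + matrix(p$dec_b1, n, model$d, byrow = TRUE)
  hd <- zd * (zd > 0)
  X_hat <- hd %*% p$dec_W2 + matrix(p$dec_b2, n, model$m, byrow = TRUE)
  out <- list(X_hat = X_hat)
  if (keep) out <- c(out, list(fs = fs, convs = convs, zd = zd, hd = hd))
  out
}

#' Exact parameter accounting
#'
#' Counts trainable parameters by component. Per layer, channel-distinct
#' operator modes contribute `(k_s + k_g) * d_emb` operator weights (1024
#' for the default k = 8, d_emb = 64) and channel-shared modes `k_s + k_g`;
#' layer-shared modes count their single tensor once. Combine counts the
#' `2d x d` affine map (plus bias) per layer; encoder/decoder count the
#' input map and the one-hidden-layer output MLP.
#'
#' @param config a [model_config].
#' @param m number of genes.
#' @return list with integer fields `operators`, `combine`, `encoder`,
#'   `decoder`, `total`.
#' @export
count_parameters <- function(config, m) {
  stopifnot(inherits(config, "model_config"))
  d <- if (config$raw_features) as.integer(m) else config$d_emb
  per_slot <- if (share_channel_shared(config$share_mode))
    config$k_s + config$k_g else (config$k_s + config$k_g) * d
  n_slots <- if (share_layer_shared(config$share_mode)) 1L else config$L
  operators <- per_slot * n_slots
  combine <- config$L * (2 * d * d + d)
  encoder <- if (config$raw_features) 0L else m * d + d
  decoder <- if (config$raw_features) 0L else (d * d + d) + (d * m + m)
  list(operators = as.integer(operators), combine = as.integer(combine),
       encoder = as.integer(encoder), decoder = as.integer(decoder),
       total = as.integer(operators + combine + encoder + decoder))
}
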