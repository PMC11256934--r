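#' Mean-aggregation GCN baseline
#'
#' A minimal graph convolutional network used as the over-smoothing
#' comparison anchor: `depth` rounds of symmetric-normalized neighbor
#' averaging `A_hat = D^-1/2 (A + I) D^-1/2` with learned per-layer linear
#' maps and ReLU, a linear input map m -> d and linear output map d -> m,
#' trained with the identical masked loss and early stopping as the path
#' model. The receptive field equals `depth` hops. Aggregation runs on the
#' union of the spatial and gene edge sets, the same information the
#' heterogeneous model sees.
#'
#' @param dataset (normalized) ground-truth [expr_dataset].
#' @param split a [make_masks] result.
#' @param hetero a [build_hetero_graph] result.
#' @param depth number of graph convolution layers, >= 1.
#' @param d_emb hidden width, default 64.
#' @param tcfg a [train_config].
#' @return list with `X_hat` (imputed matrix), `report` (`train_report`),
#'   and `embeddings` (final hidden layer, for over-smoothing diagnostics).
#' @export
baseline_gcn <- function(dataset, split, hetero, depth, d_emb = 64,
                         tcfg = train_config()) {
  stopifnot(depth >= 1)
  X_gt <- dataset$values
  X_obs <- apply_mask(dataset, split)$values
  A <- gcn_norm_adjacency(hetero)
  n <- nrow(X_gt); m <- ncol(X_gt)
  params <- with_seed(tcfg$seed, {
    p <- list(in_W = init_dense(m, d_emb), in_b = numeric(d_emb))
    for (l in seq_len(depth)) {
      p[[paste0("W_", l)]] <- init_dense(d_emb, d_emb)
      p[[paste0("b_", l)]] <- numeric(d_emb)
    }
    p$out_W <- init_dense(d_emb, m) * 0.05  # near-zero output layer, as in
    p$out_b <- numeric(m)                   # the path model
    p
  })
  # same output-bias initialization as the path model: start at the
  # per-gene observed means
  cs <- Matrix::colSums(X_obs)
  nnzc <- Matrix::colSums(X_obs != 0)
  params$out_b <- ifelse(nnzc > 0, cs / nnzc, 0)
  forward <- function(p) {
    H <- as.matrix(X_obs %*% p$in_W) + matrix(p$in_b, n, d_emb, byrow = TRUE)
    zs <- vector("list", depth); hs <- vector("list", depth + 1)
    hs[[1]] <- H
    for (l in seq_len(depth)) {
      z <- as.matrix(A %*% (hs[[l]] %*% p[[paste0("W_", l)]])) +
        matrix(p[[paste0("b_", l)]], n, d_emb, byrow = TRUE)
      zs[[l]] <- z
      hs[[l + 1]] <- z * (z > 0)
    }
    X_hat <- hs[[depth + 1]] %*% p$out_W + matrix(p$out_b, n, m, byrow = TRUE)
    list(X_hat = X_hat, zs = zs, hs = hs)
  }
  backward <- function(p, fw, dXhat) {
    g <- lapply(p, function(x) x * 0)
    g$out_W <- crossprod(fw$hs[[depth + 1]], dXhat)
    g$out_b <- colSums(dXhat)
    dH <- dXhat %*% t(p$out_W)
    for (l in rev(seq_len(depth))) {
      dz <- dH * (fw$zs[[l]] > 0)
      dAz <- as.matrix(A %*% dz)  # A symmetric
      g[[paste0("W_", l)]] <- crossprod(fw$hs[[l]], dAz)
      g[[paste0("b_", l)]] <- colSums(dz)
      dH <- dAz %*% t(p[[paste0("W_", l)]])
    }
    g$in_W <- as.matrix(Matrix::crossprod(X_obs, dH))
    g$in_b <- colSums(dH)
    g
  }
  state <- adam_init(params)
  best <- Inf; best_epoch <- 0L; best_params <- params
  train_loss <- numeric(0); val_rmse <- numeric(0)
  for (epoch in seq_len(tcfg$max_epochs)) {
    fw <- forward(params)
    loss <- masked_mse_loss(fw$X_hat, X_gt, split$train_idx)
    if (!is.finite(loss)) stop("GCN training diverged at epoch ", epoch)
    grads <- backward(params, fw,
                      masked_mse_grad(fw$X_hat, X_gt, split$train_idx))
    up <- adam_step(params, grads, state, tcfg$lr, tcfg$weight_decay)
    params <- up$params; state <- up$state
    vr <- sqrt(masked_mse_loss(fw$X_hat, X_gt, split$val_idx))
    train_loss <- c(train_loss, loss); val_rmse <- c(val_rmse, vr)
    if (vr < best) { best <- vr; best_epoch <- epoch; best_params <- params }
    if (epoch - best_epoch >= tcfg$patience) break
  }
  fw <- forward(best_params)
  report <- structure(list(train_loss = train_loss, val_rmse = val_rmse,
                           best_epoch = best_epoch,
                           stopped_epoch = length(train_loss),
                           best_val_rmse = best),
                      class = "train_report")
  list(X_hat = fw$X_hat, report = report, embeddings = fw$hs[[depth + 1]])
}

# D^-1/2 (A + I) D^-1/2 over the union of both edge sets
gcn_norm_adjacency <- function(hetero) {
  n <- hetero$spatial$n_nodes
  e <- unique(rbind(hetero$spatial$edges, hetero$gene$edges))
  i <- c(e[, 1], e[, 2], seq_len(n))
  j <- c(e[, 2], e[, 1], seq_len(n))
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  dg <- Matrix::rowSums(A)
  Dm <- Matrix::Diagonal(x = 1 / sqrt(dg))
  Dm %*% A %*% Dm
}
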