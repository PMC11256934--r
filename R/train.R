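#' Masked mean squared error
#'
#' Mean of squared prediction errors over exactly the entries in `idx`;
#' values anywhere else in either matrix are ignored.
#'
#' @param X_hat,X_target `n x m` matrices (dense or sparse).
#' @param idx integer matrix of `(cell, gene)` pairs (1-based), nonempty.
#' @return scalar loss.
#' @export
masked_mse_loss <- function(X_hat, X_target, idx) {
  idx <- as.matrix(idx)
  if (nrow(idx) == 0) stop("empty index set: masked loss undefined")
  diff <- as.numeric(X_hat[idx]) - as.numeric(X_target[idx])
  mean(diff^2)
}

# gradient of masked_mse_loss w.r.t. X_hat, as a dense n x m matrix
masked_mse_grad <- function(X_hat, X_target, idx) {
  G <- matrix(0, nrow(X_hat), ncol(X_hat))
  diff <- as.numeric(X_hat[idx]) - as.numeric(X_target[idx])
  G[idx] <- 2 * diff / nrow(idx)
  G
}

# full analytic backward pass; returns gradients named like model$params
model_backward <- function(model, X_obs, walks_s, walks_g, cache, dXhat) {
  cfg <- model$config
  p <- model$params
  g <- lapply(p, function(x) if (is.matrix(x)) x * 0 else numeric(length(x)))
  if (!cfg$raw_features) {
    # decoder: X_hat = relu(f_L W1 + b1) W2 + b2
    g$dec_W2 <- crossprod(cache$hd, dXhat)
    g$dec_b2 <- colSums(dXhat)
    dhd <- dXhat %*% t(p$dec_W2)
    dzd <- dhd * (cache$zd > 0)
    fL <- cache$fs[[cfg$L + 1]]
    g$dec_W1 <- crossprod(fL, dzd)
    g$dec_b1 <- colSums(dzd)
    df <- dzd %*% t(p$dec_W1)
  } else df <- dXhat
  d <- model$d
  for (l in rev(seq_len(cfg$L))) {
    layer <- model_layer(model, l)
    z <- cache$convs[[l]]$z
    h <- cache$convs[[l]]$h
    dz <- df * (z > 0)
    g[[paste0("W1_", l)]] <- g[[paste0("W1_", l)]] + crossprod(h, dz)
    g[[paste0("b_", l)]] <- g[[paste0("b_", l)]] + colSums(dz)
    dh <- dz %*% t(layer$W1)
    dcs <- dh[, seq_len(d), drop = FALSE]
    dcg <- dh[, d + seq_len(d), drop = FALSE]
    f_in <- cache$fs[[l]]
    slot <- op_slot(model, l)
    df <- matrix(0, nrow(f_in), d)
    if (cfg$modality == "spatial") { dcs <- dcs + dcg; dcg <- NULL }
    if (cfg$modality == "gene") { dcg <- dcg + dcs; dcs <- NULL }
    if (!is.null(dcs)) {
      bs <- path_convolve_backward(layer$op_s, walks_s, f_in, dcs)
      nm <- paste0("op_s_", slot)
      g[[nm]] <- g[[nm]] + bs$d_op
      df <- df + bs$d_f
    }
    if (!is.null(dcg)) {
      bg <- path_convolve_backward(layer$op_g, walks_g, f_in, dcg)
      nm <- paste0("op_g_", slot)
      g[[nm]] <- g[[nm]] + bg$d_op
      df <- df + bg$d_f
    }
  }
  if (!cfg$raw_features) {
    g$enc_W <- as.matrix(Matrix::crossprod(X_obs, df))
    g$enc_b <- colSums(df)
  }
  g
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (weight_decay > 0 && !grepl("^b_|_b[0-9]*$", nm))
      gr <- gr + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' @param max_epochs epoch cap, default 1000 (early stopping is the
#'   effective stopper).
#' @param patience stop when validation RMSE has not improved for this many
#'   consecutive epochs; default 50.
#' @param lr Adam learning rate, default 1e-3.
#' @param weight_decay L2 penalty on non-bias weights, default 1e-5.
#' @param seed run seed driving initialization and the per-epoch walk
#'   resampling schedule.
#' @param verbose print progress every 25 epochs.
#' @return a `train_config` list.
#' @export
train_config <- function(max_epochs = 1000, patience = 50, lr = 1e-3,
                         weight_decay = 1e-5, seed = 1L, verbose = FALSE) {
  stopifnot(patience >= 1, lr > 0, max_epochs >= 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr = lr,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 verbose = verbose),
            class = "train_config")
}

#' Train the imputation model
#'
#' Full-batch optimization of the masked MSE over training nonzero entries.
#' Each epoch resamples the walk sets on both graphs (fresh seeds from
#' [resample_schedule]), runs the forward pass on the observed (masked)
#' matrix, and takes one Adam step. Validation RMSE is tracked on the
#' validation entries; training stops once it has not improved for
#' `patience` epochs and the best-validation weights are restored. Test
#' entries influence nothing: they are zeroed in the input and excluded from
#' both losses.
#'
#' @param dataset an [expr_dataset] holding the (normalized) ground-truth
#'   matrix `X_gt`.
#' @param split a [make_masks] result over the nonzeros of `dataset`.
#' @param hetero a [build_hetero_graph] result.
#' @param mcfg a [model_config].
#' @param tcfg a [train_config].
#' @return list with `model` (trained, best-validation weights) and `report`
#'   (class `train_report`): per-epoch `train_loss` and `val_rmse`,
#'   `best_epoch`, `stopped_epoch`, `best_val_rmse`.
#' @export
train_model <- function(dataset, split, hetero, mcfg = model_config(),
                        tcfg = train_config()) {
  stopifnot(inherits(dataset, "expr_dataset"), inherits(split, "mask_split"))
  X_gt <- dataset$values
  X_obs <- apply_mask(dataset, split)$values
  model <- init_model(mcfg, ncol(X_gt), seed = tcfg$seed)
  if (!mcfg$raw_features) {
    # start the decoder bias at the per-gene observed means so early epochs
    # learn structure rather than gene abundance offsets
    cs <- Matrix::colSums(X_obs)
    nnzc <- Matrix::colSums(X_obs != 0)
    model$params$dec_b2 <- ifelse(nnzc > 0, cs / nnzc, 0)
  }
  state <- adam_init(model$params)
  train_loss <- numeric(0)
  val_rmse <- numeric(0)
  best <- Inf; best_epoch <- 0L; best_params <- model$params
  for (epoch in seq_len(tcfg$max_epochs)) {
    ws <- sample_walks(hetero$spatial, mcfg$k_s, mcfg$T_s, mcfg$q_s, mcfg$p,
                       resample_schedule(2 * epoch, tcfg$seed))
    wg <- sample_walks(hetero$gene, mcfg$k_g, mcfg$T_g, mcfg$q_g, mcfg$p,
                       resample_schedule(2 * epoch + 1, tcfg$seed))
    fw <- model_forward_cache(model, X_obs, ws, wg)
    loss <- masked_mse_loss(fw$X_hat, X_gt, split$train_idx)
    if (!is.finite(loss))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    grads <- model_backward(model, X_obs, ws, wg, fw,
                            masked_mse_grad(fw$X_hat, X_gt, split$train_idx))
    up <- adam_step(model$params, grads, state, tcfg$lr, tcfg$weight_decay)
    model$params <- up$params; state <- up$state
    vr <- sqrt(masked_mse_loss(fw$X_hat, X_gt, split$val_idx))
    train_loss <- c(train_loss, loss)
    val_rmse <- c(val_rmse, vr)
    if (vr < best) { best <- vr; best_epoch <- epoch; best_params <- model$params }
    if (tcfg$verbose && epoch %% 25 == 0)
      message(sprintf("epoch %d: train %.4f, val RMSE %.4f", epoch, loss, vr))
    if (epoch - best_epoch >= tcfg$patience) break
  }
  model$params <- best_params
  report <- structure(list(train_loss = train_loss, val_rmse = val_rmse,
                           best_epoch = best_epoch, stopped_epoch = length(train_loss),
                           best_val_rmse = best),
                      class = "train_report")
  list(model = model, report = report)
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf(
    "train_report: %d epochs, best val RMSE %.4f at epoch %d\n",
    x$stopped_epoch, x$best_val_rmse, x$best_epoch))
  invisible(x)
}

#' Impute with a trained model
#'
#' Samples fresh walks (deterministic from `seed`) and runs the forward
#' pass on the observed matrix.
#'
#' @param model a trained `path_gnn`.
#' @param X_obs observed (masked) matrix.
#' @param hetero heterogeneous graph used in training.
#' @param seed walk seed for the inference pass.
#' @return `n x m` imputed matrix.
#' @export
impute <- function(model, X_obs, hetero, seed = 0L) {
  cfg <- model$config
  ws <- sample_walks(hetero$spatial, cfg$k_s, cfg$T_s, cfg$q_s, cfg$p,
                     resample_schedule(0, seed))
  wg <- sample_walks(hetero$gene, cfg$k_g, cfg$T_g, cfg$q_g, cfg$p,
                     resample_schedule(1, seed))
  model_forward(model, X_obs, ws, wg)
}
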