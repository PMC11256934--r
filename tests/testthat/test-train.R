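small_setup <- function(seed = 1, n = 40, m = 15) {
  sim <- simulate_spatial(sim_config(n_cells = n, n_genes = m, n_layers = 2,
                                     type_mix = 1, base_rate = 2,
                                     dropout_rate = 0.3, seed = 31))
  norm <- normalize_counts(sim$dataset)
  split <- make_masks(norm, seed = seed)
  het <- build_hetero_graph(apply_mask(norm, split),
                            hvg = select_hvg(norm, 10), knn_k = 4)
  list(data = norm, split = split, het = het)
}

small_mcfg <- model_config(L = 1, d_emb = 6, k_s = 3, k_g = 3,
                           T_s = 2, T_g = 2)

test_that("masked MSE averages exactly the indexed entries", {
  X_t <- matrix(c(1, 0, 2, 3), 2, 2, byrow = TRUE)
  X_h <- matrix(c(2, 9, 2, 5), 2, 2, byrow = TRUE)
  idx <- rbind(c(1, 1), c(2, 1), c(2, 2))
  expect_equal(masked_mse_loss(X_h, X_t, idx), 5 / 3)
  # the unindexed entry (1,2) is ignored entirely
  X_h2 <- X_h; X_h2[1, 2] <- -100
  expect_equal(masked_mse_loss(X_h2, X_t, idx), 5 / 3)
  expect_equal(masked_mse_loss(X_t, X_t, idx), 0)
  expect_error(masked_mse_loss(X_h, X_t, idx[0, , drop = FALSE]), "empty")
})

test_that("analytic gradients match central finite differences", {
  s <- small_setup()
  model <- pathimpute:::init_model(small_mcfg, ncol(s$data$values), seed = 7)
  ws <- sample_walks(s$het$spatial, 3, 2, seed = 9)
  wg <- sample_walks(s$het$gene, 3, 2, seed = 10)
  X_obs <- apply_mask(s$data, s$split)$values
  X_gt <- s$data$values
  lossfn <- function(params) {
    m2 <- model; m2$params <- params
    fw <- pathimpute:::model_forward_cache(m2, X_obs, ws, wg, keep = FALSE)
    masked_mse_loss(fw$X_hat, X_gt, s$split$train_idx)
  }
  fw <- pathimpute:::model_forward_cache(model, X_obs, ws, wg)
  an <- pathimpute:::model_backward(
    model, X_obs, ws, wg, fw,
    pathimpute:::masked_mse_grad(fw$X_hat, X_gt, s$split$train_idx))
  eps <- 1e-5
  withr::with_seed(3, {
    for (nm in names(model$params)) {
      for (ii in sample(length(model$params[[nm]]),
                        min(4, length(model$params[[nm]])))) {
        pp <- model$params; pp[[nm]][ii] <- pp[[nm]][ii] + eps
        pm <- model$params; pm[[nm]][ii] <- pm[[nm]][ii] - eps
        fd <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
        rel <- abs(fd - an[[nm]][ii]) / max(abs(fd), abs(an[[nm]][ii]), 1e-8)
        expect_lt(rel, 1e-4)
      }
    }
  })
})

test_that("training runs exactly max_epochs when stopping never triggers", {
  s <- small_setup()
  fit <- train_model(s$data, s$split, s$het, small_mcfg,
                     train_config(max_epochs = 1, patience = 5, seed = 2))
  expect_equal(fit$report$stopped_epoch, 1L)
  expect_length(fit$report$train_loss, 1)
})

test_that("early stopping respects patience and restores the best epoch", {
  s <- small_setup()
  fit <- train_model(s$data, s$split, s$het, small_mcfg,
                     train_config(max_epochs = 80, patience = 10, lr = 5e-3,
                                  seed = 3))
  r <- fit$report
  expect_equal(r$best_val_rmse, min(r$val_rmse))
  expect_equal(r$best_epoch, which.min(r$val_rmse))
  expect_lte(r$stopped_epoch - r$best_epoch, 10)
})

test_that("runs are bit-reproducible from one seed", {
  s <- small_setup()
  tcfg <- train_config(max_epochs = 15, patience = 10, seed = 5)
  f1 <- train_model(s$data, s$split, s$het, small_mcfg, tcfg)
  f2 <- train_model(s$data, s$split, s$het, small_mcfg, tcfg)
  expect_identical(f1$report$train_loss, f2$report$train_loss)
  expect_identical(f1$report$val_rmse, f2$report$val_rmse)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("held-out test values cannot influence training", {
  s <- small_setup()
  tcfg <- train_config(max_epochs = 12, patience = 10, seed = 4)
  f1 <- train_model(s$data, s$split, s$het, small_mcfg, tcfg)
  tampered <- s$data
  tampered$values[s$split$test_idx] <- 999
  f2 <- train_model(tampered, s$split, s$het, small_mcfg, tcfg)
  expect_identical(f1$report$train_loss, f2$report$train_loss)
})

test_that("a trained model beats column-mean imputation on structured
           synthetic data", {
  # low-rank type-program dataset, ~30% observed
  sim <- simulate_spatial(sim_config(n_cells = 200, n_genes = 100,
                                     n_layers = 3, n_types = 3,
                                     program_rank = 3, dropout_rate = 0.65,
                                     seed = 23))
  norm <- normalize_counts(sim$dataset)
  split <- make_masks(norm, seed = 1)
  obs <- apply_mask(norm, split)
  het <- build_hetero_graph(obs, hvg = select_hvg(norm, 60), knn_k = 8)
  fit <- train_model(norm, split, het,
                     model_config(L = 2, d_emb = 16, k_s = 4, k_g = 4,
                                  T_s = 2, T_g = 2),
                     train_config(max_epochs = 250, patience = 40, lr = 1e-2,
                                  seed = 1))
  X_hat <- impute(fit$model, obs$values, het, seed = 1)
  rmse_model <- evaluate_imputation(X_hat, norm, split)$rmse
  rmse_base <- evaluate_imputation(column_mean_baseline(obs$values),
                                   norm, split)$rmse
  expect_lt(rmse_model, rmse_base)
})

test_that("model checkpoints restore a forward-identical model", {
  s <- small_setup()
  fit <- train_model(s$data, s$split, s$het, small_mcfg,
                     train_config(max_epochs = 5, patience = 5, seed = 6))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit$model, path)
  back <- load_model(path)
  obs <- apply_mask(s$data, s$split)$values
  expect_equal(impute(back, obs, s$het, seed = 2),
               impute(fit$model, obs, s$het, seed = 2), tolerance = 1e-12)
})
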