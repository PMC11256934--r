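# fixed small walk set over a 6-node graph used across model tests
fixed_instance <- function(d = 4, k = 3, T = 2, seed = 20) {
  g <- pathimpute:::new_cell_graph(
    6, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 1), c(2, 5)),
    "spatial")
  ws <- sample_walks(g, k = k, T = T, seed = seed)
  withr::with_seed(seed, f <- matrix(rnorm(6 * d), 6, d))
  list(g = g, ws = ws, f = f)
}

test_that("path convolution annihilates with zero weights and is the
           identity for k = 1, unit weight, T = 1", {
  inst <- fixed_instance()
  zero_op <- path_operator(matrix(0, 3, 4), share_mode = "op_ind")
  expect_equal(path_convolve(zero_op, inst$ws, inst$f), matrix(0, 6, 4))
  ws1 <- sample_walks(inst$g, k = 1, T = 1, seed = 3)
  one_op <- path_operator(matrix(1, 1, 4), share_mode = "op_ind")
  expect_equal(path_convolve(one_op, ws1, inst$f), inst$f)
})

test_that("path convolution equals the naive triple-loop oracle", {
  inst <- fixed_instance()
  withr::with_seed(8, W <- matrix(rnorm(12), 3, 4))
  op <- path_operator(W, share_mode = "op_ind")
  got <- path_convolve(op, inst$ws, inst$f)
  want <- oracle_path_convolve(W, inst$ws$walks, inst$ws$start_of, 2, inst$f)
  expect_equal(got, want, tolerance = 1e-6)
  # channel-shared k-vector broadcasts across channels
  v <- c(0.5, -1, 2)
  opv <- path_operator(v, share_mode = "op_cha")
  wantv <- oracle_path_convolve(matrix(v, 3, 4), inst$ws$walks,
                                inst$ws$start_of, 2, inst$f)
  expect_equal(path_convolve(opv, inst$ws, inst$f), wantv, tolerance = 1e-6)
})

test_that("path convolution is bilinear in embeddings and weights", {
  inst <- fixed_instance()
  withr::with_seed(9, {
    W1 <- matrix(rnorm(12), 3, 4); W2 <- matrix(rnorm(12), 3, 4)
    f2 <- matrix(rnorm(24), 6, 4)
  })
  op1 <- path_operator(W1, share_mode = "op_ind")
  op2 <- path_operator(W2, share_mode = "op_ind")
  lhs <- path_convolve(op1, inst$ws, 2 * inst$f - 3 * f2)
  rhs <- 2 * path_convolve(op1, inst$ws, inst$f) -
    3 * path_convolve(op1, inst$ws, f2)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  opsum <- path_operator(W1 + W2, share_mode = "op_ind")
  expect_equal(path_convolve(opsum, inst$ws, inst$f),
               path_convolve(op1, inst$ws, inst$f) +
                 path_convolve(op2, inst$ws, inst$f),
               tolerance = 1e-10)
})

test_that("relabeling nodes permutes the convolution output identically", {
  inst <- fixed_instance()
  withr::with_seed(30, perm <- sample(6))
  # apply perm to graph/walks/f: node i becomes perm[i]
  ws_p <- inst$ws
  ws_p$walks <- matrix(perm[inst$ws$walks], nrow(inst$ws$walks))
  ws_p$start_of <- perm[inst$ws$start_of]
  # reorder rows so they are grouped by the new start labels
  ord <- order(ws_p$start_of)
  ws_p$walks <- ws_p$walks[ord, ]; ws_p$start_of <- ws_p$start_of[ord]
  f_p <- matrix(0, 6, 4); f_p[perm, ] <- inst$f
  withr::with_seed(8, W <- matrix(rnorm(12), 3, 4))
  op <- path_operator(W, share_mode = "op_ind")
  out <- path_convolve(op, inst$ws, inst$f)
  out_p <- path_convolve(op, ws_p, f_p)
  expect_equal(out_p[perm, ], out, tolerance = 1e-10)
})

test_that("layer forward matches its compositional oracle", {
  inst <- fixed_instance()
  wg <- sample_walks(inst$g, k = 3, T = 2, seed = 77)
  withr::with_seed(14, {
    Ws <- matrix(rnorm(12), 3, 4); Wg <- matrix(rnorm(12), 3, 4)
    W1 <- matrix(rnorm(8 * 5), 8, 5); b <- rnorm(5)
  })
  layer <- list(op_s = path_operator(Ws, "spatial", "op_ind"),
                op_g = path_operator(Wg, "gene", "op_ind"),
                W1 = W1, b = b)
  got <- layer_forward(layer, inst$ws, wg, inst$f)
  cs <- oracle_path_convolve(Ws, inst$ws$walks, inst$ws$start_of, 2, inst$f)
  cg <- oracle_path_convolve(Wg, wg$walks, wg$start_of, 2, inst$f)
  want <- pmax(cbind(cs, cg) %*% W1 +
                 matrix(b, 6, 5, byrow = TRUE), 0)
  expect_equal(got, want, tolerance = 1e-6)
  expect_true(all(got >= 0))
  # annihilator and zero-input closed forms
  layer0 <- layer; layer0$W1 <- W1 * 0
  expect_equal(layer_forward(layer0, inst$ws, wg, inst$f),
               matrix(pmax(b, 0), 6, 5, byrow = TRUE), tolerance = 1e-12)
  expect_equal(layer_forward(layer, inst$ws, wg, inst$f * 0),
               matrix(pmax(b, 0), 6, 5, byrow = TRUE), tolerance = 1e-12)
})

test_that("model forward is deterministic given walks and finite-checked", {
  inst <- fixed_instance()
  wg <- sample_walks(inst$g, k = 3, T = 2, seed = 55)
  mcfg <- model_config(L = 2, d_emb = 4, k_s = 3, k_g = 3, T_s = 2, T_g = 2)
  model <- pathimpute:::init_model(mcfg, 7, seed = 5)
  withr::with_seed(6, X <- matrix(rpois(42, 2), 6, 7))
  a <- model_forward(model, X, inst$ws, wg)
  b <- model_forward(model, X, inst$ws, wg)
  expect_identical(a, b)
  Xbad <- X; Xbad[1, 1] <- NaN
  expect_error(model_forward(model, Xbad, inst$ws, wg), "finite")
  # zeroed decoder output layer annihilates the prediction
  m0 <- model
  m0$params$dec_W2 <- m0$params$dec_W2 * 0
  m0$params$dec_b2 <- m0$params$dec_b2 * 0
  expect_equal(model_forward(m0, X, inst$ws, wg), matrix(0, 6, 7))
})

test_that("a single-layer model equals the hand-chained oracle", {
  inst <- fixed_instance()
  wg <- sample_walks(inst$g, k = 3, T = 2, seed = 60)
  mcfg <- model_config(L = 1, d_emb = 4, k_s = 3, k_g = 3, T_s = 2, T_g = 2)
  model <- pathimpute:::init_model(mcfg, 4, seed = 9)
  withr::with_seed(61, X <- matrix(rpois(24, 3), 6, 4))
  p <- model$params
  f0 <- X %*% p$enc_W + matrix(p$enc_b, 6, 4, byrow = TRUE)
  cs <- oracle_path_convolve(p$op_s_1, inst$ws$walks, inst$ws$start_of, 2, f0)
  cg <- oracle_path_convolve(p$op_g_1, wg$walks, wg$start_of, 2, f0)
  f1 <- pmax(cbind(cs, cg) %*% p$W1_1 + matrix(p$b_1, 6, 4, byrow = TRUE), 0)
  hd <- pmax(f1 %*% p$dec_W1 + matrix(p$dec_b1, 6, 4, byrow = TRUE), 0)
  want <- hd %*% p$dec_W2 + matrix(p$dec_b2, 6, 4, byrow = TRUE)
  expect_equal(model_forward(model, X, inst$ws, wg), want, tolerance = 1e-5)
})

test_that("operator parameter counts follow the sharing-mode formulas", {
  cfg <- model_config(L = 1, k_s = 8, k_g = 8, d_emb = 64)
  expect_equal(count_parameters(cfg, 100)$operators, (8 + 8) * 64)
  # op_glo is independent of depth
  g1 <- model_config(L = 1, share_mode = "op_glo")
  g4 <- model_config(L = 4, share_mode = "op_glo")
  expect_equal(count_parameters(g1, 50)$operators,
               count_parameters(g4, 50)$operators)
  # counts ordered across modes at fixed config
  counts <- vapply(c("op_glo", "op_cha", "op_lay", "op_ind"), function(mode)
    count_parameters(model_config(L = 3, share_mode = mode), 50)$operators,
    integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("parameter counts agree with enumerating the live registry", {
  for (mode in c("op_glo", "op_cha", "op_lay", "op_ind")) {
    cfg <- model_config(L = 3, d_emb = 6, k_s = 4, k_g = 3,
                        share_mode = mode)
    model <- pathimpute:::init_model(cfg, 11, seed = 1)
    pc <- count_parameters(cfg, 11)
    p <- model$params
    is_op <- grepl("^op_", names(p))
    expect_equal(sum(lengths(p[is_op])), pc$operators, info = mode)
    is_comb <- grepl("^(W1|b)_", names(p))
    expect_equal(sum(lengths(p[is_comb])), pc$combine, info = mode)
    expect_equal(sum(lengths(p)), pc$total, info = mode)
  }
})

test_that("with k = 1, T = 1, unit op a layer is a dense map on [f, f]", {
  g <- fixed_instance()$g
  ws1 <- sample_walks(g, k = 1, T = 1, seed = 1)
  withr::with_seed(19, {
    f <- matrix(rnorm(18), 6, 3)
    W1 <- matrix(rnorm(6 * 3), 6, 3); b <- rnorm(3)
  })
  layer <- list(op_s = path_operator(matrix(1, 1, 3), "spatial", "op_ind"),
                op_g = path_operator(matrix(1, 1, 3), "gene", "op_ind"),
                W1 = W1, b = b)
  got <- layer_forward(layer, ws1, ws1, f)
  want <- pmax(cbind(f, f) %*% W1 + matrix(b, 6, 3, byrow = TRUE), 0)
  expect_equal(got, want, tolerance = 1e-12)
})
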