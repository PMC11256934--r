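# spatial autocorrelation of a vector over a k-NN coordinate graph
# (Moran-like: correlation between a cell's value and its neighbor mean)
spatial_autocor <- function(values, coords, k = 6) {
  nb <- oracle_knn(coords, k)
  nbmean <- vapply(seq_len(nrow(nb)),
                   function(i) mean(values[nb[i, ]]), numeric(1))
  cor(values, nbmean)
}

test_that("simulation is deterministic per seed and satisfies dataset
           invariants", {
  cfg <- sim_config(n_cells = 80, n_genes = 30, seed = 5)
  a <- simulate_spatial(cfg)
  b <- simulate_spatial(cfg)
  expect_identical(as.matrix(a$dataset$values), as.matrix(b$dataset$values))
  expect_identical(a$dataset$coords, b$dataset$coords)
  ds <- a$dataset
  expect_gte(min(ds$values), 0)
  expect_equal(nrow(ds$coords), nrow(ds$values))
  expect_false(anyDuplicated(ds$cell_ids) > 0)
  expect_true(all(a$truth$rate >= 0))
  expect_length(ds$layer_labels, nrow(ds$values))
})

test_that("observed density matches the closed-form expectation", {
  sim <- simulate_spatial(sim_config(n_cells = 500, n_genes = 200,
                                     dropout_rate = 0.75, seed = 9))
  got <- Matrix::nnzero(sim$dataset$values) / prod(dim(sim$dataset$values))
  expect_lt(abs(got - sim$truth$expected_density), 0.03)
})

test_that("pure type structure gives stronger within- than between-layer
           correlation", {
  sim <- simulate_spatial(sim_config(n_cells = 100, n_genes = 40,
                                     n_layers = 2, type_mix = 1,
                                     program_rank = 0,
                                     spatial_signal_scale = 0,
                                     noise_scale = 0, dropout_rate = 0,
                                     seed = 13))
  X <- as.matrix(normalize_counts(sim$dataset)$values)
  lab <- sim$truth$layer_labels
  cc <- cor(t(X))
  same <- outer(lab, lab, "==") & upper.tri(cc)
  diff <- outer(lab, lab, "!=") & upper.tri(cc)
  expect_gt(mean(cc[same]), mean(cc[diff]))
})

test_that("observed density decreases monotonically in dropout rate", {
  dens <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(dr) {
    mean(vapply(1:3, function(s) {
      sim <- simulate_spatial(sim_config(n_cells = 120, n_genes = 60,
                                         dropout_rate = dr, seed = 100 + s))
      Matrix::nnzero(sim$dataset$values) / (120 * 60)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(dens) < 0))
})

test_that("fixtures have their declared shapes and structure", {
  tiny <- make_fixture("tiny")
  expect_equal(dim(tiny$dataset$values), c(30L, 20L))
  expect_error(make_fixture("nope"), "tiny, layered, smooth_only, type_only")
  layered <- make_fixture("layered")
  expect_equal(dim(layered$dataset$values), c(500L, 200L))
  dens <- Matrix::nnzero(layered$dataset$values) / (500 * 200)
  expect_gt(dens, 0.15); expect_lt(dens, 0.40)
})

test_that("type_only scrambles coordinates but not expression", {
  seedy <- 21
  plain <- simulate_spatial(sim_config(n_cells = 300, n_genes = 120,
                                       n_layers = 3,
                                       spatial_signal_scale = 0,
                                       type_signal_scale = 2.5,
                                       seed = seedy))
  scram <- make_fixture("type_only", seed = seedy)
  expect_identical(as.matrix(scram$dataset$values),
                   as.matrix(plain$dataset$values))
  expect_false(identical(scram$dataset$coords, plain$dataset$coords))
  expect_setequal(unname(scram$dataset$coords[, 1]),
                  unname(plain$dataset$coords[, 1]))
})

test_that("smooth_only carries more spatial autocorrelation than
           type_only", {
  smooth <- make_fixture("smooth_only", seed = 3)
  scram <- make_fixture("type_only", seed = 3)
  g <- 1  # marker gene; any gene carries the smooth field in smooth_only
  a_smooth <- spatial_autocor(log1p(as.matrix(smooth$dataset$values)[, g]),
                              smooth$dataset$coords)
  a_scram <- spatial_autocor(log1p(as.matrix(scram$dataset$values)[, g]),
                             scram$dataset$coords)
  expect_gt(a_smooth, a_scram)
})
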