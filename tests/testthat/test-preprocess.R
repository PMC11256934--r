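test_that("lognorm scales each cell to the target total then log1p", {
  ds <- expr_dataset(matrix(c(1, 1, 0), 1, 3))
  out <- normalize_counts(ds, scale_factor = 2)
  expect_equal(as.numeric(out$values), c(log(2), log(2), 0))
  expect_identical(normalize_counts(ds, scheme = "none"), ds)
})

test_that("normalization never changes the nonzero pattern", {
  ds <- random_dataset(20, 30, seed = 9)
  out <- normalize_counts(ds)
  expect_equal(as.matrix(out$values != 0), as.matrix(ds$values != 0))
})

test_that("all-zero cells are left untouched with a warning", {
  X <- matrix(c(0, 0, 1, 2), 2, 2, byrow = TRUE)
  expect_warning(out <- normalize_counts(expr_dataset(X)), "all-zero")
  expect_equal(as.numeric(out$values[1, ]), c(0, 0))
})

test_that("HVG selection ranks by dispersion with a 3100-gene default", {
  expect_equal(eval(formals(select_hvg)$n_hvg), 3100)
  # constant gene excluded in favor of a varying one
  X <- cbind(rep(5, 10), c(rep(0, 5), rep(10, 5)))
  sel <- select_hvg(expr_dataset(X), n_hvg = 1)
  expect_equal(sel$gene_indices, 2L)
  # agreement with an independent dispersion-ranking oracle
  ds <- random_dataset(25, 10, seed = 21)
  sel3 <- select_hvg(ds, n_hvg = 3)
  expect_equal(sel3$gene_indices, oracle_hvg_rank(ds$values)[1:3])
  expect_warning(all_sel <- select_hvg(ds, n_hvg = 99), "exceeds")
  expect_equal(all_sel$n_hvg, 10L)
})

test_that("masks hold round(frac*Z) entries and partition the nonzeros", {
  ds <- random_dataset(20, 20, density = 0.25, seed = 2)
  Z <- Matrix::nnzero(ds$values)
  split <- make_masks(ds, seed = 1)
  expect_equal(nrow(split$test_idx), round(0.1 * Z))
  expect_equal(nrow(split$val_idx), round(0.1 * Z))
  all_idx <- rbind(split$test_idx, split$val_idx, split$train_idx)
  keys <- paste(all_idx[, 1], all_idx[, 2])
  expect_false(anyDuplicated(keys) > 0)
  trip <- Matrix::summary(ds$values)
  expect_setequal(keys, paste(trip$i, trip$j))
  # no zero entry ever appears in a mask
  expect_true(all(ds$values[all_idx] != 0))
})

test_that("a matrix with exactly 100 nonzeros splits 10/10/80 by default", {
  withr::with_seed(5, {
    X <- matrix(0, 10, 20)
    X[sample(200, 100)] <- rpois(100, 3) + 1
  })
  split <- make_masks(expr_dataset(X), seed = 8)
  expect_equal(nrow(split$test_idx), 10)
  expect_equal(nrow(split$val_idx), 10)
  expect_equal(nrow(split$train_idx), 80)
})

test_that("degenerate fractions, reproducibility, and seed sensitivity", {
  ds <- random_dataset(25, 40, seed = 31)
  Z <- Matrix::nnzero(ds$values)
  all_train <- make_masks(ds, test_frac = 0, val_frac = 0, seed = 1)
  expect_equal(nrow(all_train$train_idx), Z)
  expect_equal(nrow(all_train$test_idx), 0)
  s1 <- make_masks(ds, seed = 17)
  s2 <- make_masks(ds, seed = 17)
  expect_identical(s1$test_idx, s2$test_idx)
  expect_identical(s1$train_idx, s2$train_idx)
  s3 <- make_masks(ds, seed = 18)
  expect_false(identical(s1$test_idx, s3$test_idx))
})

test_that("mask-size rounding resolves ties downward and fractions are
           validated", {
  expect_equal(pathimpute:::round_half_down(10.5), 10L)
  expect_equal(pathimpute:::round_half_down(10.6), 11L)
  ds <- expr_dataset(matrix(c(1, 0, 0, 0), 2, 2))
  expect_error(make_masks(ds, test_frac = 0.6, val_frac = 0.4, seed = 1),
               "< 1")
  expect_error(make_masks(expr_dataset(matrix(0, 2, 2)), seed = 1),
               "nonzero")
})

test_that("apply_mask zeroes exactly the held-out entries", {
  X <- matrix(c(1, 2, 0, 3), 2, 2, byrow = TRUE)
  ds <- expr_dataset(X)
  split <- structure(list(
    test_idx = matrix(c(1L, 2L), 1, dimnames = list(NULL, c("cell", "gene"))),
    val_idx = matrix(integer(0), 0, 2),
    train_idx = matrix(c(1L, 2L, 1L, 2L), 2),
    seed = 1L, fractions = c(test = 1 / 3, val = 0)), class = "mask_split")
  out <- apply_mask(ds, split)
  expect_equal(as.matrix(out$values),
               matrix(c(1, 0, 0, 3), 2, 2, byrow = TRUE), ignore_attr = TRUE)
  # input untouched
  expect_equal(as.numeric(ds$values[1, 2]), 2)
})

test_that("masking changes |test|+|val| entries and is idempotent", {
  ds <- random_dataset(30, 30, seed = 12)
  split <- make_masks(ds, seed = 4)
  obs <- apply_mask(ds, split)
  changed <- sum(as.matrix(obs$values) != as.matrix(ds$values))
  expect_equal(changed, nrow(split$test_idx) + nrow(split$val_idx))
  again <- apply_mask(obs, split)
  expect_equal(as.matrix(again$values), as.matrix(obs$values))
  # empty masks leave the matrix alone
  empty <- make_masks(ds, test_frac = 0, val_frac = 0, seed = 1)
  expect_equal(as.matrix(apply_mask(ds, empty)$values),
               as.matrix(ds$values))
  # out-of-bounds indices are rejected
  bad <- split; bad$test_idx[1, 1] <- 99L
  expect_error(apply_mask(ds, bad), "bounds")
})

test_that("masking commutes with normalization on the nonzero pattern", {
  ds <- random_dataset(15, 25, seed = 77)
  split <- make_masks(ds, seed = 2)
  a <- apply_mask(normalize_counts(ds), split)$values != 0
  b <- apply_mask(ds, split)$values != 0
  expect_equal(as.matrix(a), as.matrix(b))
})
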