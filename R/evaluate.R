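#' Extract held-out entries as aligned vectors
#'
#' Pulls the entries named by `idx` out of the imputed and ground-truth
#' matrices in a deterministic row-major order (by cell, then gene), so the
#' two vectors are index-aligned.
#'
#' @param X_hat,X_gt `n x m` matrices.
#' @param idx integer matrix of `(cell, gene)` pairs, 1-based, nonempty.
#' @return list with numeric vectors `pred` and `truth` of length
#'   `nrow(idx)`.
#' @export
extract_masked_vectors <- function(X_hat, X_gt, idx) {
  idx <- as.matrix(idx)
  if (nrow(idx) == 0) stop("empty index set")
  if (min(idx) < 1 || max(idx[, 1]) > nrow(X_gt) || max(idx[, 2]) > ncol(X_gt))
    stop("index out of bounds")
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  list(pred = as.numeric(X_hat[idx]), truth = as.numeric(X_gt[idx]))
}

#' Imputation accuracy metrics
#'
#' The three benchmark metrics over aligned prediction/truth vectors:
#' mean absolute error (L1 distance per entry), cosine similarity, and root
#' mean squared error.
#'
#' @param pred,truth equal-length numeric vectors (length >= 1).
#' @param l1 `"mean"` (default, per-entry scale) or `"sum"`.
#' @return object of class `metric_report`: list with `l1_distance`,
#'   `cosine_similarity`, `rmse`, `n_entries`.
#' @export
compute_metrics <- function(pred, truth, l1 = c("mean", "sum")) {
  l1 <- match.arg(l1)
  stopifnot(length(pred) == length(truth), length(pred) >= 1)
  np <- sqrt(sum(pred^2)); nt <- sqrt(sum(truth^2))
  if (np == 0 || nt == 0)
    stop("cosine similarity undefined for a zero-norm vector")
  abs_err <- abs(pred - truth)
  structure(list(
    l1_distance = if (l1 == "mean") mean(abs_err) else sum(abs_err),
    cosine_similarity = sum(pred * truth) / (np * nt),
    rmse = sqrt(mean((pred - truth)^2)),
    n_entries = length(pred)),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "metric_report (N=%d): L1 %.4f, cosine %.4f, RMSE %.4f\n",
    x$n_entries, x$l1_distance, x$cosine_similarity, x$rmse))
  invisible(x)
}

#' Score an imputed matrix on the test mask
#'
#' @param X_hat imputed matrix.
#' @param dataset ground-truth [expr_dataset] (same scale as `X_hat`).
#' @param split a [make_masks] result; metrics use `split$test_idx`.
#' @return a [compute_metrics] report.
#' @export
evaluate_imputation <- function(X_hat, dataset, split) {
  v <- extract_masked_vectors(X_hat, dataset$values, split$test_idx)
  compute_metrics(v$pred, v$truth)
}

#' Column-mean imputation baseline
#'
#' Predicts every entry of a gene by the mean of that gene's observed
#' (unmasked) nonzero entries — the standard no-graph reference point.
#'
#' @param X_obs observed matrix (held-out entries zeroed).
#' @return `n x m` matrix of per-gene observed means.
#' @export
column_mean_baseline <- function(X_obs) {
  cs <- Matrix::colSums(X_obs)
  nnz <- Matrix::colSums(X_obs != 0)
  mu <- ifelse(nnz > 0, cs / nnz, 0)
  matrix(mu, nrow(X_obs), ncol(X_obs), byrow = TRUE)
}
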