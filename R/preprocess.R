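#' Library-size normalize an expression matrix
#'
#' Scales each cell's counts to a fixed total and applies `log(1 + x)`.
#' Zero entries remain exactly zero, so the nonzero set — and therefore any
#' mask drawn over it — is unchanged by normalization.
#'
#' @param data an [expr_dataset] of nonnegative counts.
#' @param scheme `"lognorm"` (default) or `"none"` (identity).
#' @param scale_factor per-cell target total before the log, default `1e4`.
#' @return an [expr_dataset] with transformed values.
#' @export
normalize_counts <- function(data, scheme = c("lognorm", "none"),
                             scale_factor = 1e4) {
  stopifnot(inherits(data, "expr_dataset"))
  scheme <- match.arg(scheme)
  if (scheme == "none") return(data)
  rs <- Matrix::rowSums(data$values)
  zero_cells <- rs == 0
  if (any(zero_cells)) {
    warning(sum(zero_cells), " all-zero cell(s) left unnormalized")
    rs[zero_cells] <- 1  # factor irrelevant: no nonzero entries to scale
  }
  v <- Matrix::Diagonal(x = scale_factor / rs) %*% data$values
  v <- methods::as(methods::as(v, "CsparseMatrix"), "generalMatrix")
  v@x <- log1p(v@x)
  expr_dataset(v, data$cell_ids, data$gene_ids, data$coords, data$layer_labels)
}

#' Select highly variable genes
#'
#' Ranks genes by a dispersion statistic (variance / mean of library-size
#' normalized counts) and returns the top `n_hvg`. Deterministic: ties are
#' broken by ascending gene index; all-zero genes rank last.
#'
#' @param data an [expr_dataset] (raw or normalized counts).
#' @param n_hvg number of genes to keep, default 3100.
#' @return an object of class `hvg_selection`: list with `gene_indices`
#'   (1-based, ordered by decreasing dispersion) and `n_hvg`.
#' @export
select_hvg <- function(data, n_hvg = 3100) {
  stopifnot(inherits(data, "expr_dataset"), n_hvg >= 1)
  m <- ncol(data$values)
  if (n_hvg > m) {
    warning("n_hvg = ", n_hvg, " exceeds ", m, " genes; keeping all")
    n_hvg <- m
  }
  rs <- Matrix::rowSums(data$values)
  rs[rs == 0] <- 1
  v <- Matrix::Diagonal(x = 1e4 / rs) %*% data$values
  mu <- Matrix::colMeans(v)
  ex2 <- Matrix::colMeans(v^2)
  n <- nrow(v)
  vr <- (ex2 - mu^2) * n / max(n - 1, 1)
  disp <- ifelse(mu > 0, vr / mu, -Inf)
  ord <- order(-disp, seq_len(m))
  structure(list(gene_indices = ord[seq_len(n_hvg)], n_hvg = n_hvg),
            class = "hvg_selection")
}

round_half_down <- function(x) as.integer(ceiling(x - 0.5))

#' Create a train/validation/test masking of nonzero entries
#'
#' Samples `round(test_frac * Z)` and `round(val_frac * Z)` of the `Z`
#' nonzero entries uniformly at random without replacement (disjointly);
#' everything else is training. Rounding ties resolve downward. The three
#' sets partition the nonzero set exactly.
#'
#' @param data an [expr_dataset] holding the ground-truth matrix.
#' @param test_frac,val_frac held-out fractions, defaults 0.10 each.
#' @param seed integer seed making the draw reproducible.
#' @return an object of class `mask_split`: list with `test_idx`, `val_idx`,
#'   `train_idx` (integer matrices, columns `cell`,`gene`, 1-based), `seed`,
#'   `fractions`.
#' @export
make_masks <- function(data, test_frac = 0.10, val_frac = 0.10, seed = 1L) {
  stopifnot(inherits(data, "expr_dataset"))
  if (test_frac + val_frac >= 1) stop("test_frac + val_frac must be < 1")
  trip <- Matrix::summary(data$values)
  Z <- nrow(trip)
  if (Z < 1) stop("matrix has no nonzero entries to mask")
  n_test <- round_half_down(test_frac * Z)
  n_val <- round_half_down(val_frac * Z)
  if (n_test + n_val > Z)
    stop("requested ", n_test, " test + ", n_val, " val entries but only ",
         Z, " nonzeros")
  entries <- cbind(cell = trip$i, gene = trip$j)
  # canonical row-major order so output is a pure function of (matrix, seed)
  entries <- entries[order(entries[, 1], entries[, 2]), , drop = FALSE]
  perm <- with_seed(seed, sample.int(Z))
  test_rows <- perm[seq_len(n_test)]
  val_rows <- if (n_val > 0) perm[n_test + seq_len(n_val)] else integer(0)
  train_rows <- perm[-seq_len(n_test + n_val)]
  if (n_test + n_val == 0) train_rows <- perm
  take <- function(r) {
    out <- entries[r, , drop = FALSE]
    out[order(out[, 1], out[, 2]), , drop = FALSE]
  }
  structure(list(test_idx = take(test_rows), val_idx = take(val_rows),
                 train_idx = take(train_rows), seed = as.integer(seed),
                 fractions = c(test = test_frac, val = val_frac)),
            class = "mask_split")
}

#' @export
print.mask_split <- function(x, ...) {
  cat(sprintf("mask_split: %d test / %d val / %d train (seed %d)\n",
              nrow(x$test_idx), nrow(x$val_idx), nrow(x$train_idx), x$seed))
  invisible(x)
}

#' Zero out held-out entries
#'
#' Returns a copy of the dataset whose test and validation entries are set to
#' zero — the observed matrix the model is trained on. The input is not
#' modified.
#'
#' @param data an [expr_dataset] (the ground truth).
#' @param split a [make_masks] result.
#' @return an [expr_dataset] with the held-out entries zeroed.
#' @export
apply_mask <- function(data, split) {
  stopifnot(inherits(data, "expr_dataset"), inherits(split, "mask_split"))
  idx <- rbind(split$test_idx, split$val_idx)
  v <- data$values
  if (nrow(idx) > 0) {
    if (max(idx[, 1]) > nrow(v) || max(idx[, 2]) > ncol(v) || min(idx) < 1)
      stop("mask index out of bounds for ", nrow(v), " x ", ncol(v), " matrix")
    v[idx] <- 0
    v <- Matrix::drop0(v)
  }
  expr_dataset(v, data$cell_ids, data$gene_ids, data$coords, data$layer_labels)
}

#' Serialize a mask split to JSON
#'
#' Index pairs are written 0-based as `[cell, gene]` lists.
#' @param split a `mask_split`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_masks <- function(split, path) {
  to0 <- function(m) {
    if (nrow(m) == 0) return(list())
    lapply(seq_len(nrow(m)), function(r) as.integer(m[r, ] - 1L))
  }
  jsonlite::write_json(
    list(seed = split$seed,
         fractions = as.list(split$fractions),
         test = to0(split$test_idx), val = to0(split$val_idx),
         train = to0(split$train_idx)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mask split from JSON written by [write_masks]
#' @param path JSON path.
#' @return a `mask_split`.
#' @export
read_masks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  from0 <- function(m) {
    if (length(m) == 0) return(matrix(integer(0), 0, 2,
                                      dimnames = list(NULL, c("cell", "gene"))))
    m <- matrix(as.integer(unlist(m)), ncol = 2, byrow = is.list(m)) + 1L
    colnames(m) <- c("cell", "gene")
    m
  }
  structure(list(test_idx = from0(obj$test), val_idx = from0(obj$val),
                 train_idx = from0(obj$train), seed = as.integer(obj$seed),
                 fractions = unlist(obj$fractions)),
            class = "mask_split")
}

# Run code under a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
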