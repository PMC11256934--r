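# Independent brute-force oracles used across the suite. These deliberately
# use naive loops and base primitives, never the package's own vectorized
# code paths.

# all pairs within threshold, O(n^2) scan
oracle_spatial_edges <- function(coords, d_thr) {
  n <- nrow(coords)
  out <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sqrt(sum((coords[i, ] - coords[j, ])^2)) <= d_thr)
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# k nearest rows by Euclidean distance, full sort, ties by index
oracle_knn <- function(mat, k) {
  n <- nrow(mat)
  t(vapply(seq_len(n), function(i) {
    d <- apply(mat, 1, function(r) sqrt(sum((r - mat[i, ])^2)))
    d[i] <- Inf
    order(d, seq_len(n))[seq_len(k)]
  }, integer(k)))
}

# path convolution by explicit (node, walk, position, channel) loops
oracle_path_convolve <- function(W, walks, start_of, T_walks, f) {
  n <- nrow(f); d <- ncol(f); k <- ncol(walks)
  out <- matrix(0, n, d)
  for (w in seq_len(nrow(walks))) {
    v <- start_of[w]
    for (j in seq_len(d)) {
      s <- 0
      for (i in seq_len(k)) s <- s + W[i, j] * f[walks[w, i], j]
      out[v, j] <- out[v, j] + s / T_walks
    }
  }
  out
}

# entry extraction by explicit loop in row-major order
oracle_extract <- function(X_hat, X_gt, idx) {
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  pred <- numeric(nrow(idx)); truth <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    pred[r] <- X_hat[idx[r, 1], idx[r, 2]]
    truth[r] <- X_gt[idx[r, 1], idx[r, 2]]
  }
  list(pred = pred, truth = truth)
}

# per-gene dispersion ranking re-implemented independently (library-size
# normalization to 1e4, variance/mean, ties by index)
oracle_hvg_rank <- function(X) {
  X <- as.matrix(X)
  rs <- rowSums(X); rs[rs == 0] <- 1
  V <- sweep(X, 1, 1e4 / rs, "*")
  disp <- apply(V, 2, function(col) {
    if (mean(col) == 0) -Inf else var(col) / mean(col)
  })
  order(-disp, seq_len(ncol(X)))
}

# small random sparse count dataset with coordinates
random_dataset <- function(n, m, density = 0.4, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rpois(n * m, 2) * (runif(n * m) < density), n, m)
    if (sum(X) == 0) X[1, 1] <- 1
    expr_dataset(X, coords = matrix(runif(2 * n, 0, 10), n, 2))
  })
}

# undirected edge set as a canonical sorted matrix, for set comparison
edge_key <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  a <- pmin(edges[, 1], edges[, 2]); b <- pmax(edges[, 1], edges[, 2])
  sort(paste(a, b))
}

# hand-built hetero graph from two edge lists
hetero_from_edges <- function(n, es, eg) {
  structure(list(
    spatial = pathimpute:::new_cell_graph(n, es, "spatial"),
    gene = pathimpute:::new_cell_graph(n, eg, "gene")),
    class = "hetero_graph")
}
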