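#' @title Cell graphs
#' @description A `cell_graph` is an undirected simple graph over the n cells:
#'   list with `n_nodes`, `edges` (integer e x 2 matrix, each row an unordered
#'   pair i < j, 1-based, no self loops, no duplicates) and `kind`
#'   (`"spatial"` or `"gene"`). The heterogeneous graph pairs one of each kind
#'   over the same nodes.
#' @name cell_graph
NULL

new_cell_graph <- function(n_nodes, edges, kind) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, c(2, 1)]
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    if (any(edges[, 1] == edges[, 2])) stop("self-loop in edge set")
    if (min(edges) < 1 || max(edges) > n_nodes) stop("edge index out of range")
  }
  colnames(edges) <- c("i", "j")
  structure(list(n_nodes = as.integer(n_nodes), edges = edges, kind = kind),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("cell_graph (%s): %d nodes, %d edges, mean degree %.2f\n",
              x$kind, x$n_nodes, nrow(x$edges),
              if (x$n_nodes > 0) 2 * nrow(x$edges) / x$n_nodes else 0))
  invisible(x)
}

#' Build the spatial proximity graph
#'
#' Connects two cells whenever their Euclidean distance is at most `d_thr`.
#' With `d_thr = NULL` the threshold is chosen automatically as the smallest
#' pairwise distance that yields mean degree >= `target_degree` (default 6,
#' the hexagonal-lattice neighbor count of Visium arrays).
#'
#' @param coords numeric n x 2 coordinate matrix.
#' @param d_thr positive distance threshold, or `NULL` for automatic choice.
#' @param target_degree mean degree targeted by the automatic threshold.
#' @return a spatial [cell_graph].
#' @export
build_spatial_graph <- function(coords, d_thr = NULL, target_degree = 6) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, all(is.finite(coords)))
  n <- nrow(coords)
  if (n < 2)
    return(new_cell_graph(n, matrix(integer(0), 0, 2), "spatial"))
  d <- stats::dist(coords)
  if (is.null(d_thr)) {
    # mean degree >= t  <=>  |E| >= t*n/2: take the (t*n/2)-th smallest distance
    need <- min(ceiling(target_degree * n / 2), length(d))
    d_thr <- sort(d, partial = need)[need]
  }
  if (d_thr <= 0) stop("d_thr must be positive")
  dm <- as.matrix(d)
  hit <- which(upper.tri(dm) & dm <= d_thr, arr.ind = TRUE)
  g <- new_cell_graph(n, hit, "spatial")
  attr(g, "d_thr") <- d_thr
  g
}

#' Build the expression-similarity graph
#'
#' For each cell, its `knn_k` nearest cells under Euclidean distance on the
#' highly-variable-gene expression vectors form a directed top-k relation;
#' the stored undirected edge set is the symmetrized union (an edge exists if
#' either endpoint selects the other). A cell is never its own neighbor.
#' Distance ties at the k-th neighbor break by ascending cell index, so the
#' build is deterministic.
#'
#' @param hvg_matrix numeric n x h matrix of HVG expression per cell.
#' @param knn_k neighbors per cell, must satisfy `knn_k < n`.
#' @return a gene [cell_graph]; the directed neighbor lists are kept in
#'   `attr(, "knn")` (n x k integer matrix) for diagnostics.
#' @export
build_gene_graph <- function(hvg_matrix, knn_k = 6) {
  hvg_matrix <- as.matrix(hvg_matrix)
  n <- nrow(hvg_matrix)
  stopifnot(knn_k >= 1, knn_k < n)
  # squared Euclidean distances via the Gram expansion
  sq <- rowSums(hvg_matrix^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(hvg_matrix)
  d2[d2 < 0] <- 0
  diag(d2) <- Inf  # self-distance excluded
  knn <- matrix(0L, n, knn_k)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ], seq_len(n))  # ties -> ascending index
    knn[i, ] <- ord[seq_len(knn_k)]
  }
  edges <- cbind(rep(seq_len(n), each = knn_k), as.integer(t(knn)))
  g <- new_cell_graph(n, edges, "gene")
  attr(g, "knn") <- knn
  g
}

#' Build the heterogeneous graph
#'
#' Composes the spatial threshold graph and the HVG k-nearest-neighbor graph
#' over the same cells.
#'
#' @param data an [expr_dataset] with coordinates.
#' @param hvg a [select_hvg] result (computed from `data` when `NULL`).
#' @param d_thr spatial threshold (`NULL` = automatic, see
#'   [build_spatial_graph]).
#' @param knn_k gene-graph neighbors per cell, default 6.
#' @param verbose print edge-count summaries.
#' @return an object of class `hetero_graph`: list with `spatial` and `gene`
#'   [cell_graph]s.
#' @export
build_hetero_graph <- function(data, hvg = NULL, d_thr = NULL, knn_k = 6,
                               verbose = FALSE) {
  stopifnot(inherits(data, "expr_dataset"), !is.null(data$coords))
  if (is.null(hvg)) hvg <- select_hvg(data, n_hvg = min(3100, ncol(data$values)))
  gs <- build_spatial_graph(data$coords, d_thr)
  hvg_mat <- as.matrix(data$values[, hvg$gene_indices, drop = FALSE])
  gg <- build_gene_graph(hvg_mat, knn_k)
  out <- structure(list(spatial = gs, gene = gg), class = "hetero_graph")
  if (verbose) print(out)
  out
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat("hetero_graph over", x$spatial$n_nodes, "cells\n  ")
  print(x$spatial)
  cat("  ")
  print(x$gene)
  invisible(x)
}

#' Serialize graphs as an edge-list TSV
#'
#' Columns `node1`, `node2` (0-based) and `kind`; loads back bit-exactly.
#' @param graph a `cell_graph` or `hetero_graph`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path) {
  rows <- function(g) if (nrow(g$edges) == 0)
    data.frame(node1 = integer(0), node2 = integer(0), kind = character(0))
  else data.frame(node1 = g$edges[, 1] - 1L, node2 = g$edges[, 2] - 1L,
                  kind = g$kind)
  df <- if (inherits(graph, "hetero_graph"))
    rbind(rows(graph$spatial), rows(graph$gene)) else rows(graph)
  n <- if (inherits(graph, "hetero_graph")) graph$spatial$n_nodes
       else graph$n_nodes
  con <- file(path, "w")
  writeLines(paste0("# n_nodes=", n), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read an edge-list TSV written by [write_graph]
#' @param path TSV path.
#' @return a `cell_graph` or `hetero_graph` matching what was written.
#' @export
read_graph <- function(path) {
  header <- readLines(path, n = 1)
  n <- as.integer(sub("# n_nodes=", "", header, fixed = TRUE))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                          stringsAsFactors = FALSE)
  kinds <- unique(df$kind)
  mk <- function(k) new_cell_graph(
    n, as.matrix(df[df$kind == k, c("node1", "node2")]) + 1L, k)
  if (setequal(kinds, c("spatial", "gene")))
    structure(list(spatial = mk("spatial"), gene = mk("gene")),
              class = "hetero_graph")
  else mk(kinds[1])
}

# adjacency in 0-based CSR form for the C++ walk sampler
graph_csr <- function(graph) {
  n <- graph$n_nodes
  e <- graph$edges
  from <- c(e[, 1], e[, 2]); to <- c(e[, 2], e[, 1])
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]
  indptr <- cumsum(c(0L, tabulate(from, nbins = n)))
  list(indptr = as.integer(indptr), indices = as.integer(to - 1L))
}

# neighbor list (1-based) used by R-side checks
graph_adj <- function(graph) {
  csr <- graph_csr(graph)
  lapply(seq_len(graph$n_nodes), function(i) {
    cnt <- csr$indptr[i + 1] - csr$indptr[i]
    csr$indices[csr$indptr[i] + seq_len(cnt)] + 1L
  })
}
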