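#' Sample biased random walks from every node
#'
#' Draws `T` second-order (Node2Vec) random walks of fixed node-length `k`
#' starting from every node of the graph. Given the previous node, the next
#' step is drawn over the current node's neighbors with unnormalized weights
#' 1/p (return to the previous node), 1 (move to a common neighbor of the
#' previous node) and 1/q (move outward); the first hop is uniform. `k`
#' counts nodes, so a length-`k` walk makes `k - 1` hops. Isolated nodes
#' self-pad (the walk repeats the node).
#'
#' @param graph a [cell_graph].
#' @param k walk node-length, >= 1.
#' @param T walks per start node, >= 1.
#' @param q in-out bias (> 0): larger values keep the walk local.
#' @param p return bias (> 0), default 1.
#' @param seed integer seed; walks are reproducible given `(graph, seed)`.
#' @return an object of class `walk_set`: list with `walks` (integer
#'   `(n*T) x k` matrix of 1-based node indices, rows grouped by start node),
#'   `start_of` (length `n*T` start node of each row), `graph_kind`, `k`,
#'   `T`, `q`, `p`, `seed`.
#' @export
sample_walks <- function(graph, k, T, q = 1, p = 1, seed = 1L) {
  stopifnot(inherits(graph, "cell_graph"), k >= 1, T >= 1, q > 0, p > 0)
  csr <- graph_csr(graph)
  n <- graph$n_nodes
  deg <- diff(csr$indptr)
  if (any(deg == 0))
    message(sum(deg == 0), " isolated node(s): walks self-pad")
  w <- sample_walks_cpp(csr$indptr, csr$indices, n, as.integer(k),
                        as.integer(T), p, q, as.integer(seed) %% 2147483647L)
  structure(list(walks = w + 1L,
                 start_of = rep(seq_len(n), each = T),
                 graph_kind = graph$kind, k = as.integer(k),
                 T = as.integer(T), q = q, p = p, seed = as.integer(seed)),
            class = "walk_set")
}

#' @export
print.walk_set <- function(x, ...) {
  cat(sprintf("walk_set (%s): %d walks of length %d (T=%d, q=%g, p=%g)\n",
              x$graph_kind, nrow(x$walks), x$k, x$T, x$q, x$p))
  invisible(x)
}

#' Per-epoch walk seed schedule
#'
#' Deterministic mapping from `(epoch, base_seed)` to the seed used to
#' resample walks that epoch, so a full training run is reproducible from one
#' seed while every epoch sees fresh paths. Distinct epochs map to distinct
#' seeds (the map is affine and injective modulo a prime larger than any
#' epoch count).
#'
#' @param epoch nonnegative integer epoch index.
#' @param base_seed integer run seed.
#' @return integer seed in `[0, 2^31)`.
#' @export
resample_schedule <- function(epoch, base_seed) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- (abs(as.numeric(base_seed)) * 48271) %% m
  as.integer((s + as.numeric(epoch) * 69621 + 1) %% m)
}

#' Dump a walk set as a TSV table
#' @param ws a `walk_set`; @param path output path.
#' @return `path`, invisibly.
#' @export
write_walks <- function(ws, path) {
  df <- data.frame(start = ws$start_of - 1L, ws$walks - 1L)
  colnames(df) <- c("start", paste0("pos", seq_len(ws$k)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
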