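#' Construct an expression dataset
#'
#' Bundles a cells-by-genes nonnegative expression matrix with per-cell 2-D
#' spatial coordinates and identifiers. This is the container every other
#' stage of the package consumes; orientation is fixed as cells x genes.
#'
#' @param values numeric matrix or `Matrix::sparseMatrix`, n cells x m genes,
#'   nonnegative.
#' @param cell_ids character vector of n unique cell/spot barcodes.
#' @param gene_ids character vector of m unique gene identifiers.
#' @param coords numeric n x 2 matrix of spatial coordinates (platform units),
#'   one row per cell, aligned to `cell_ids`. May be `NULL` for expression-only
#'   use.
#' @param layer_labels optional per-cell categorical annotation (synthetic
#'   ground-truth tissue layers); `NULL` for real data.
#'
#' @return An object of class `expr_dataset`: a list with fields `values`,
#'   `cell_ids`, `gene_ids`, `coords`, `layer_labels`.
#' @export
expr_dataset <- function(values, cell_ids = NULL, gene_ids = NULL,
                         coords = NULL, layer_labels = NULL) {
  values <- as_sparse(values)
  n <- nrow(values); m <- ncol(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(m))
  cell_ids <- as.character(cell_ids); gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != n) stop("cell_ids length ", length(cell_ids),
                                  " does not match ", n, " rows")
  if (length(gene_ids) != m) stop("gene_ids length ", length(gene_ids),
                                  " does not match ", m, " columns")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (min_nonzero(values) < 0) stop("expression values must be nonnegative")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    if (nrow(coords) != n) stop("coords has ", nrow(coords),
                                " rows for ", n, " cells")
    if (ncol(coords) != 2) stop("coords must have exactly 2 columns")
    if (!all(is.finite(coords))) stop("coords must be finite")
    rownames(coords) <- cell_ids
  }
  if (!is.null(layer_labels) && length(layer_labels) != n)
    stop("layer_labels length mismatch")
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 coords = coords, layer_labels = layer_labels),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  nz <- Matrix::nnzero(x$values)
  cat(sprintf("expr_dataset: %d cells x %d genes, %d nonzero (density %.3f)\n",
              nrow(x$values), ncol(x$values), nz,
              nz / prod(dim(x$values))))
  if (!is.null(x$coords)) cat("  spatial coordinates: yes\n")
  if (!is.null(x$layer_labels))
    cat("  layer labels:", paste(levels(factor(x$layer_labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

as_sparse <- function(values) {
  if (inherits(values, "sparseMatrix")) {
    methods::as(methods::as(values, "CsparseMatrix"), "generalMatrix")
  } else {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                            "CsparseMatrix"), "generalMatrix")
  }
}

# smallest stored value (0 if any structural zero present in a dense sense)
min_nonzero <- function(x) {
  if (length(x@x) == 0) return(0)
  min(x@x)
}
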