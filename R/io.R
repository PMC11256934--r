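#' Read an expression count matrix
#'
#' Reads a cells-by-genes matrix from Matrix Market, CSV, or AnnData h5ad.
#' Orientation is always cells x genes; files stored genes x cells (the raw
#' 10x convention) must be flagged with `transpose = TRUE` — orientation is
#' never guessed.
#'
#' @param path path to the matrix file (`.mtx`, `.csv`, or `.h5ad`).
#' @param format one of `"mtx"`, `"csv"`, `"h5ad"`; default inferred from the
#'   file extension.
#' @param transpose logical; set `TRUE` when the file stores genes as rows.
#' @return an [expr_dataset] (without coordinates).
#' @details For `mtx`, sidecar files `barcodes.tsv` (cells) and
#'   `features.tsv` or `genes.tsv` (genes) are picked up from the same
#'   directory when present. Sparsity of the input is preserved.
#' @export
read_counts <- function(path, format = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", h5ad = "h5ad",
                     stop("cannot infer format from extension of ", path))
  }
  format <- match.arg(format, c("mtx", "csv", "h5ad"))
  out <- switch(format,
    mtx = read_counts_mtx(path),
    csv = read_counts_csv(path),
    h5ad = read_counts_h5ad(path))
  if (transpose) {
    out <- expr_dataset(Matrix::t(out$values), cell_ids = out$gene_ids,
                        gene_ids = out$cell_ids)
  }
  if (min_nonzero(out$values) < 0)
    stop("negative expression values in ", path)
  out
}

read_counts_mtx <- function(path) {
  values <- tryCatch(Matrix::readMM(path),
                     error = function(e) stop("malformed Matrix Market file ",
                                              path, ": ", conditionMessage(e)))
  dir <- dirname(path)
  read_side <- function(fnames) {
    for (f in file.path(dir, fnames)) if (file.exists(f)) {
      return(utils::read.delim(f, header = FALSE,
                               stringsAsFactors = FALSE)[[1]])
    }
    NULL
  }
  cells <- read_side(c("barcodes.tsv"))
  genes <- read_side(c("features.tsv", "genes.tsv"))
  expr_dataset(values, cell_ids = cells, gene_ids = genes)
}

read_counts_csv <- function(path) {
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  expr_dataset(as.matrix(tab), cell_ids = rownames(tab),
               gene_ids = colnames(tab))
}

#' Write an expression count matrix
#'
#' Inverse of [read_counts]; round-trips the sparse nonzero set losslessly.
#'
#' @param data an [expr_dataset].
#' @param path output file path; for `mtx` the sidecars `barcodes.tsv` and
#'   `features.tsv` are written next to it.
#' @param format one of `"mtx"`, `"csv"`, `"h5ad"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_counts <- function(data, path, format = NULL) {
  stopifnot(inherits(data, "expr_dataset"))
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", h5ad = "h5ad",
                     stop("cannot infer format from extension of ", path))
  }
  format <- match.arg(format, c("mtx", "csv", "h5ad"))
  switch(format,
    mtx = {
      Matrix::writeMM(data$values, path)
      dir <- dirname(path)
      utils::write.table(data$cell_ids, file.path(dir, "barcodes.tsv"),
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
      utils::write.table(data$gene_ids, file.path(dir, "features.tsv"),
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
    },
    csv = {
      dense <- as.matrix(data$values)
      dimnames(dense) <- list(data$cell_ids, data$gene_ids)
      utils::write.csv(dense, path)
    },
    h5ad = write_counts_h5ad(data, path))
  invisible(path)
}

# Minimal AnnData on-disk support (cells as observations): X stored dense or
# as csr/csc group with indptr/indices/data; obs/var names from _index.
read_counts_h5ad <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("h5ad support requires the rhdf5 package")
  h5 <- rhdf5::h5ls(path)
  obs_names <- h5ad_names(path, "obs")
  var_names <- h5ad_names(path, "var")
  x_entries <- h5[h5$group == "/X", "name"]
  if (length(x_entries) == 0) {
    X <- rhdf5::h5read(path, "X")           # dense: stored var x obs (HDF5 is
    X <- Matrix::t(Matrix::Matrix(X, sparse = TRUE))  # column-major) -> transpose
  } else {
    attrs <- rhdf5::h5readAttributes(path, "X")
    enc <- as.character(attrs[["encoding-type"]])[1]
    shape <- as.integer(unlist(attrs[["shape"]]))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    vals <- as.numeric(rhdf5::h5read(path, "X/data"))
    if (isTRUE(enc == "csr_matrix")) {
      X <- Matrix::sparseMatrix(j = indices + 1L, p = indptr, x = vals,
                                dims = shape)
    } else {
      X <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = vals,
                                dims = shape)
    }
  }
  expr_dataset(X, cell_ids = obs_names, gene_ids = var_names)
}

h5ad_names <- function(path, grp) {
  attrs <- tryCatch(rhdf5::h5readAttributes(path, grp),
                    error = function(e) list())
  idx <- attrs[["_index"]]
  if (is.null(idx)) idx <- "_index"
  as.character(rhdf5::h5read(path, paste0(grp, "/", idx)))
}

write_counts_h5ad <- function(data, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("h5ad support requires the rhdf5 package")
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  X <- methods::as(data$values, "RsparseMatrix")  # CSR over cells
  rhdf5::h5createGroup(path, "X")
  rhdf5::h5write(X@x, path, "X/data")
  rhdf5::h5write(X@j, path, "X/indices")
  rhdf5::h5write(X@p, path, "X/indptr")
  h5f <- rhdf5::H5Fopen(path)
  h5g <- rhdf5::H5Gopen(h5f, "X")
  rhdf5::h5writeAttribute("csr_matrix", h5g, "encoding-type")
  rhdf5::h5writeAttribute(dim(data$values), h5g, "shape")
  rhdf5::H5Gclose(h5g)
  for (grp in c("obs", "var")) {
    rhdf5::h5createGroup(h5f, grp)
    nm <- if (grp == "obs") data$cell_ids else data$gene_ids
    rhdf5::h5write(nm, h5f, paste0(grp, "/_index"))
    h5g <- rhdf5::H5Gopen(h5f, grp)
    rhdf5::h5writeAttribute("_index", h5g, "_index")
    rhdf5::H5Gclose(h5g)
  }
  rhdf5::H5Fclose(h5f)
  invisible(path)
}

#' Read spatial coordinates
#'
#' Reads a CSV/TSV table (header row required) with one row per cell and two
#' numeric coordinate columns, and aligns rows to the cell order of the count
#' matrix by id when an id column is present.
#'
#' @param path coordinate table path.
#' @param cell_ids optional character vector giving the cell order of the
#'   counts; required for id-based realignment and mismatch detection.
#' @return numeric n x 2 matrix aligned to `cell_ids` (or file order).
#' @export
read_coords <- function(path, cell_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  numcol <- vapply(tab, is.numeric, logical(1))
  if (sum(numcol) < 2)
    stop("coordinate parse error: need two numeric columns, found ",
         sum(numcol), " in ", path)
  ids <- NULL
  idcol <- which(!numcol)
  if (length(idcol) > 0) ids <- as.character(tab[[idcol[1]]])
  xy <- as.matrix(tab[, which(numcol)[1:2], drop = FALSE])
  storage.mode(xy) <- "double"
  if (!is.null(cell_ids)) {
    if (is.null(ids)) {
      if (nrow(xy) != length(cell_ids))
        stop("alignment error: ", nrow(xy), " coordinate rows for ",
             length(cell_ids), " cells and no id column")
    } else {
      miss <- setdiff(cell_ids, ids)
      if (length(miss) > 0)
        stop("alignment error: coordinates missing for cells ",
             paste(utils::head(miss, 5), collapse = ", "))
      xy <- xy[match(cell_ids, ids), , drop = FALSE]
      ids <- cell_ids
    }
    rownames(xy) <- cell_ids
  } else if (!is.null(ids)) rownames(xy) <- ids
  colnames(xy) <- c("x", "y")
  xy
}

#' Write spatial coordinates as CSV
#' @param coords n x 2 matrix with cell ids as rownames.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_coords <- function(coords, path) {
  df <- data.frame(cell = rownames(coords), x = coords[, 1], y = coords[, 2])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
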