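#' Construct an expression matrix container
#'
#' Wraps a gene x cell count matrix (dense or sparse) together with gene and
#' cell identifiers, a normalization flag, and the pseudocount used in log
#' transforms downstream. Genes are rows, cells are columns.
#'
#' @param counts A numeric matrix or `Matrix::dgCMatrix` of non-negative
#'   values, genes in rows and cells in columns. Dimnames, if present, seed
#'   the gene/cell identifiers.
#' @param genes Character vector of gene identifiers (unique). Defaults to
#'   rownames of `counts` or `gene1..geneG`.
#' @param cells Character vector of cell identifiers (unique). Defaults to
#'   colnames of `counts` or `cell1..cellN`.
#' @param normalized Logical; has library-size normalization been applied?
#' @param pseudocount Scalar added inside log transforms (default 1).
#'
#' @return An object of class `expression_matrix` with elements `counts`
#'   (a `dgCMatrix`), `genes`, `cells`, `normalized`, `pseudocount`.
#' @export
expression_matrix <- function(counts, genes = NULL, cells = NULL,
                              normalized = FALSE, pseudocount = 1) {
  if (is.null(genes)) genes <- rownames(counts)
  if (is.null(cells)) cells <- colnames(counts)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(cells)) cells <- paste0("cell", seq_len(ncol(counts)))
  genes <- as.character(genes)
  cells <- as.character(cells)
  if (length(genes) != nrow(counts))
    stop("structural error: ", length(genes), " gene identifiers for ",
         nrow(counts), " matrix rows")
  if (length(cells) != ncol(counts))
    stop("structural error: ", length(cells), " cell identifiers for ",
         ncol(counts), " matrix columns")
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  if (anyDuplicated(cells)) stop("duplicate cell identifiers")
  if (!methods::is(counts, "Matrix"))
    counts <- Matrix::Matrix(counts * 1.0, sparse = TRUE, doDiag = FALSE)
  # force a general CsparseMatrix (symmetric input must not share dimnames)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("negative values in count matrix")
  dimnames(counts) <- list(genes, cells)
  structure(
    list(counts = counts, genes = genes, cells = cells,
         normalized = isTRUE(normalized), pseudocount = pseudocount),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells (%s), sparsity %.1f%%\n",
              length(x$genes), length(x$cells),
              if (x$normalized) "normalized" else "raw counts",
              100 * sparsity(x)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' Fraction of zero entries
#'
#' @param x An `expression_matrix` or matrix-like object.
#' @return Scalar in \[0, 1\]: `1 - nnz / (rows * cols)` exactly (explicitly
#'   stored zeros are counted as zeros).
#' @export
sparsity <- function(x) {
  m <- if (inherits(x, "expression_matrix")) x$counts else x
  nnz <- if (methods::is(m, "sparseMatrix")) sum(m@x != 0) else sum(m != 0)
  1 - nnz / (as.numeric(nrow(m)) * as.numeric(ncol(m)))
}

#' Expressed-gene mask
#'
#' A gene counts as expressed when detected (non-zero) in at least
#' `min_cells` cells. All-zero genes are retained in the container but
#' excluded from differential expression and correlation through this mask.
#'
#' @param x An `expression_matrix`.
#' @param min_cells Minimum number of detecting cells (default 5).
#' @return Named logical vector over genes.
#' @export
expressed_genes <- function(x, min_cells = 5) {
  det <- Matrix::rowSums(x$counts != 0)
  stats::setNames(det >= min_cells, x$genes)
}

#' Library-size normalization
#'
#' Scales every cell to the mean library size of the dataset (per-cell scale
#' factor = mean library / cell library). Cells with a zero library are
#' removed with a warning.
#'
#' @param x An `expression_matrix` of raw counts.
#' @return A normalized `expression_matrix` (`normalized = TRUE`).
#' @export
normalize_counts <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  libs <- Matrix::colSums(x$counts)
  keep <- libs > 0
  if (!all(keep)) {
    warning(sum(!keep), " cell(s) with zero library size removed")
    x$counts <- x$counts[, keep, drop = FALSE]
    x$cells <- x$cells[keep]
    libs <- libs[keep]
  }
  sf <- mean(libs) / libs
  counts <- x$counts %*% Matrix::Diagonal(x = sf)
  dimnames(counts) <- list(x$genes, x$cells)
  x$counts <- methods::as(counts, "CsparseMatrix")
  x$normalized <- TRUE
  x
}

#' Log-normalized dense expression values
#'
#' `log2(normalized counts + pseudocount)`, used for cell-cell distances and
#' highly-variable-gene selection. Returns a dense base matrix.
#'
#' @param x An `expression_matrix`.
#' @param genes Optional gene subset (names or indices).
#' @param cells Optional cell subset.
#' @return Dense numeric matrix.
#' @keywords internal
log_expr <- function(x, genes = NULL, cells = NULL) {
  m <- x$counts
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  log2(as.matrix(m) + x$pseudocount)
}

#' Subset an expression matrix
#'
#' @param x An `expression_matrix`.
#' @param i,j Gene / cell indices or names.
#' @param ... Unused.
#' @export
`[.expression_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$genes)
  if (missing(j)) j <- seq_along(x$cells)
  expression_matrix(x$counts[i, j, drop = FALSE],
                    normalized = x$normalized, pseudocount = x$pseudocount)
}
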