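#' Read a count matrix
#'
#' Supports the 10x-style Matrix Market triplet layout (a directory holding
#' `matrix.mtx`, `genes.tsv` (or `features.tsv`) and `barcodes.tsv`) and
#' dense TSV/CSV with a header row of cell identifiers and gene identifiers
#' in the first column.
#'
#' @param path Directory (Matrix Market layout) or file (dense table).
#' @param format One of `"auto"`, `"mtx"`, `"tsv"`, `"csv"`.
#' @return An `expression_matrix` of raw counts. All-zero genes are retained
#'   (see [expressed_genes()]).
#' @export
read_counts <- function(path, format = c("auto", "mtx", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx"
    else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  if (format == "mtx") {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop("parse error: no matrix.mtx under ", path)
    gf <- file.path(path, "genes.tsv")
    if (!file.exists(gf)) gf <- file.path(path, "features.tsv")
    bf <- file.path(path, "barcodes.tsv")
    if (!file.exists(gf) || !file.exists(bf))
      stop("structural error: genes/features.tsv or barcodes.tsv missing under ", path)
    m <- Matrix::readMM(mtx)
    genes <- utils::read.delim(gf, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.delim(bf, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
      stop("structural error: identifier files do not match matrix dimensions (",
           length(genes), " genes vs ", nrow(m), " rows; ",
           length(cells), " cells vs ", ncol(m), " cols)")
    return(expression_matrix(m, genes = genes, cells = cells))
  }
  sep <- if (format == "csv") "," else "\t"
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e))
  )
  expression_matrix(as.matrix(tab), genes = rownames(tab), cells = colnames(tab))
}

#' Write a count matrix
#'
#' @param x An `expression_matrix`.
#' @param path Output directory (`format = "mtx"`) or file.
#' @param format `"mtx"`, `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("mtx", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(x$counts, file.path(path, "matrix.mtx"))
    utils::write.table(data.frame(x$genes, x$genes),
                       file.path(path, "genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(x$cells), file.path(path, "barcodes.tsv"),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    sep <- if (format == "csv") "," else "\t"
    dense <- as.matrix(x$counts)
    utils::write.table(data.frame(gene = x$genes, dense, check.names = FALSE),
                       path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Each line: set name, description, then tab-separated member genes.
#' Duplicate members within a line are dropped.
#'
#' @param path GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `universe` (all genes appearing in any set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop("parse error: GMT line ", bad[1], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  gene_set_collection(sets)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
      stop("set names must be present and unique")
    if (any(vapply(sets, function(s) any(!nzchar(s)), TRUE)))
      stop("empty gene identifier in a set")
  }
  structure(list(sets = sets,
                 universe = unique(unlist(sets, use.names = FALSE))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, %d genes in universe\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a regulator annotation
#'
#' A flat file of genes annotated as regulators of gene expression
#' (e.g. the descendants-closed membership of GO:0010468). One- or
#' two-column TSV; the first column is taken as the gene identifier.
#'
#' @param path TSV file.
#' @return Character vector of regulator gene identifiers.
#' @export
read_regulators <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  unique(as.character(tab[[1]]))
}

#' Read a gene essentiality table
#'
#' Two-column TSV: gene identifier and essentiality status. Status may be
#' logical, 0/1, or the strings "E"/"NE", "essential"/"non-essential"
#' (case-insensitive).
#'
#' @param path TSV file (header optional; auto-detected when the second
#'   field of the first line is not parseable as a status).
#' @return Tibble with columns `gene` (character) and `essential` (logical),
#'   one row per gene.
#' @export
read_essentiality <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  parse_status <- function(v) {
    v <- tolower(trimws(as.character(v)))
    out <- rep(NA, length(v))
    out[v %in% c("true", "1", "e", "essential", "yes")] <- TRUE
    out[v %in% c("false", "0", "ne", "non-essential", "nonessential", "no")] <- FALSE
    out
  }
  st <- parse_status(tab[[2]])
  if (is.na(st[1]) && nrow(tab) > 1 && !all(is.na(st[-1]))) {
    tab <- tab[-1, , drop = FALSE]   # header row
    st <- st[-1]
  }
  if (anyNA(st)) stop("parse error: unrecognized essentiality status at row ",
                      which(is.na(st))[1])
  out <- tibble::tibble(gene = as.character(tab[[1]]), essential = st)
  out <- dplyr::distinct(out, .data$gene, .keep_all = TRUE)
  out
}

#' Case-insensitive identifier matcher
#'
#' Gene identifiers are case-sensitive everywhere inside the package; this
#' helper is for the boundary with external gene sets or essentiality tables
#' (mouse symbols are capitalized differently from human ones).
#'
#' @param x Query identifiers.
#' @param table Reference identifiers.
#' @return Integer positions of `x` in `table` after case folding (NA when
#'   absent).
#' @export
match_genes_ci <- function(x, table) match(toupper(x), toupper(table))

#' Write a network as a weighted edge-list TSV
#'
#' @param net An `igraph` network (edge attribute `weight`).
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network as GraphML
#'
#' @param net An `igraph` network.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
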