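#' Highly variable genes for a set of cells
#'
#' Ranks genes by their excess coefficient of variation over a rolling-median
#' CV-vs-mean trend computed across the given cells, so that the selection is
#' re-derived for every branch of the recursive clustering.
#'
#' @param expr A normalized `expression_matrix`.
#' @param cells Cell indices or names (default: all).
#' @param n_hvg Number of genes to return (default 500; fewer if fewer pass).
#' @return Character vector of gene identifiers, most variable first. Fewer
#'   than 10 passing genes signals that the branch cannot be clustered
#'   further.
#' @export
highly_variable_genes <- function(expr, cells = NULL, n_hvg = 500) {
  if (is.null(cells)) cells <- seq_along(expr$cells)
  cells <- resolve_cells(expr, cells)
  m <- expr$counts[, cells, drop = FALSE]
  mu <- Matrix::rowMeans(m)
  ex2 <- Matrix::rowMeans(m^2)
  v <- pmax(0, (ex2 - mu^2) * length(cells) / max(1, length(cells) - 1))
  det <- Matrix::rowSums(m != 0)
  # barely detected genes carry only sampling noise in their CV estimate
  pass <- which(mu > 0 & v > 0 & det >= min(5, length(cells) / 4))
  if (length(pass) < 10) return(character(0))
  cv <- sqrt(v[pass]) / mu[pass]
  # rolling-median CV-vs-mean trend; the excess over the local trend keeps
  # mean-driven counting noise from dominating the ranking
  ord <- order(mu[pass])
  win <- min(101L, 2L * (length(pass) %/% 2L) - 1L)
  trend <- numeric(length(pass))
  trend[ord] <- stats::runmed(cv[ord], max(3L, win))
  excess <- log(cv) - log(pmax(trend, .Machine$double.eps))
  sel <- pass[order(excess, decreasing = TRUE)]
  expr$genes[utils::head(sel, n_hvg)]
}

#' Choose the tree-cut level from a cluster-count sequence
#'
#' The dendrogram is evaluated at the nine decile levels; `counts[k]` is the
#' number of clusters obtained at the k-th level (non-decreasing in k since
#' deeper levels cut closer to the leaves). The rule: at the first position
#' where the count strictly increases twice in a row, cut at the level just
#' before the first of those two increases. If the pattern never occurs the
#' tree is cut at the median level (index 5).
#'
#' @param counts Integer vector of cluster counts at the 9 decile levels.
#' @return The chosen level index (1-9).
#' @export
choose_cut_level <- function(counts) {
  stopifnot(length(counts) == 9)
  inc <- diff(counts) > 0            # inc[k]: increase from level k to k+1
  two <- which(inc[-length(inc)] & inc[-1])
  if (length(two) == 0) return(5L)
  # first k with increases (k -> k+1) and (k+1 -> k+2): cut just before, at k
  as.integer(two[1])
}

#' Cut a Ward dendrogram at decile levels with the two-increases rule
#'
#' Cut heights are evenly spaced fractions of the tree height (level k
#' cuts at `(1 - k/10) * max height`), so level 1 is nearest the root
#' (fewest clusters) and level 9 nearest the leaves; cluster counts are
#' therefore non-decreasing with the level. Spacing the levels on the
#' height axis (rather than on the merge-height multiset, whose mass sits
#' at the leaves) is what makes shallow levels yield the few, major
#' clusters.
#'
#' @param hc An `hclust` object (Ward linkage over the HVG distances).
#' @return List with `labels` (integer cluster labels at the chosen cut),
#'   `level` (chosen decile index, the heterogeneity proxy), and `counts`
#'   (the 9-level cluster-count sequence).
#' @export
cut_tree_elbow <- function(hc) {
  n <- length(hc$order)
  if (n < 2)
    return(list(labels = rep(1L, n), level = 1L, counts = rep(1L, 9)))
  hts <- (1 - (1:9) / 10) * max(hc$height)
  counts <- vapply(hts, function(h) max(stats::cutree(hc, h = h)), 0L)
  level <- choose_cut_level(counts)
  list(labels = stats::cutree(hc, h = hts[level]), level = level,
       counts = counts)
}

ward_tree <- function(expr, cells, hvg) {
  le <- log_expr(expr, genes = hvg, cells = cells)
  cc <- suppressWarnings(stats::cor(le))
  cc[is.na(cc)] <- 0
  stats::hclust(stats::as.dist(1 - cc), method = "ward.D2")
}

#' Recursive Ward clustering with per-branch HVG re-selection
#'
#' Segregates cells into the maximum number of informative clusters: each
#' cluster is re-clustered with its own freshly computed set of highly
#' variable genes until no meaningful separation remains. A branch is
#' re-clustered only if it holds at least `2 * min_size` cells, or if its
#' unsupervised cut level is at or beyond `het_level` (small groups are
#' split only when very heterogeneous). Children smaller than `min_size`
#' are merged into the sibling with the nearest centroid.
#'
#' @param expr A normalized `expression_matrix` (typically restricted to
#'   expressed genes).
#' @param min_size Lowest allowed partition size. Default: 50 when the
#'   dataset has fewer than 5000 cells, else `ceiling(n / 100)`.
#' @param max_depth Maximum recursion depth (default 6).
#' @param n_hvg Highly variable genes per branch (default 500).
#' @param het_level Decile cut level at or beyond which a small branch
#'   counts as heterogeneous (default 6).
#' @return A `cluster_tree`: `assignments` (named character vector of leaf
#'   labels along cells), `tree` (nested record), `min_size`.
#' @export
recursive_cluster <- function(expr, min_size = NULL, max_depth = 6,
                              n_hvg = 500, het_level = 6) {
  n <- length(expr$cells)
  if (is.null(min_size)) min_size <- if (n < 5000) 50L else ceiling(n / 100)
  labels <- rep(NA_character_, n)
  counter <- new.env(); counter$k <- 0L

  make_leaf <- function(cells, reason) {
    counter$k <- counter$k + 1L
    lab <- paste0("c", counter$k)
    labels[cells] <<- lab
    list(label = lab, n = length(cells), leaf = TRUE, reason = reason)
  }

  descend <- function(cells, depth, is_root) {
    if (depth >= max_depth) return(make_leaf(cells, "max_depth"))
    if (length(cells) < 4) return(make_leaf(cells, "too_few_cells"))
    hvg <- highly_variable_genes(expr, cells, n_hvg)
    if (length(hvg) < 10) return(make_leaf(cells, "no_variable_genes"))
    hc <- ward_tree(expr, cells, hvg)
    cut <- cut_tree_elbow(hc)
    heterogeneous <- cut$level >= het_level
    if (length(cells) < 2 * min_size && !heterogeneous)
      return(make_leaf(cells, "homogeneous_small"))
    kids <- cut$labels
    if (max(kids) == 1 && is_root) kids <- stats::cutree(hc, k = 2)
    kids <- merge_small_children(expr, cells, kids, min_size)
    if (max(kids) == 1) return(make_leaf(cells, "no_separation"))
    children <- lapply(sort(unique(kids)), function(k)
      descend(cells[kids == k], depth + 1, FALSE))
    list(n = length(cells), leaf = FALSE, cut_level = cut$level,
         n_hvg = length(hvg), children = children)
  }

  tree <- descend(seq_len(n), 0L, TRUE)
  structure(list(assignments = stats::setNames(labels, expr$cells),
                 tree = tree, min_size = min_size),
            class = "cluster_tree")
}

merge_small_children <- function(expr, cells, kids, min_size) {
  repeat {
    sizes <- table(kids)
    if (length(sizes) <= 1) return(kids)
    small <- names(sizes)[sizes < min_size]
    if (length(small) == 0) return(kids)
    sub <- expr$counts[, cells, drop = FALSE]
    cent <- vapply(names(sizes), function(k)
      log2(Matrix::rowMeans(sub[, kids == as.integer(k), drop = FALSE]) +
             expr$pseudocount),
      numeric(nrow(sub)))
    d <- 1 - suppressWarnings(stats::cor(cent))
    d[is.na(d)] <- 2
    diag(d) <- Inf
    worst <- small[which.min(sizes[small])]
    target <- names(sizes)[which.min(d[worst, ])]
    kids[kids == as.integer(worst)] <- as.integer(target)
  }
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster_tree: %d cells in %d leaf clusters (min_size %d)\n",
              length(x$assignments), length(unique(x$assignments)),
              x$min_size))
  invisible(x)
}

#' Cluster assignments as a tibble
#' @param x A `cluster_tree`.
#' @param ... Unused.
#' @return Tibble with columns `cell`, `cluster`.
#' @export
tidy.cluster_tree <- function(x, ...) {
  tibble::tibble(cell = names(x$assignments),
                 cluster = unname(x$assignments))
}

#' Write cluster assignments (two-column TSV) and the tree (JSON)
#' @param x A `cluster_tree`.
#' @param path Output TSV for assignments.
#' @param tree_path Optional JSON path for the nested tree record.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(x, path, tree_path = NULL) {
  utils::write.table(tidy.cluster_tree(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(tree_path))
    jsonlite::write_json(x$tree, tree_path, auto_unbox = TRUE)
  invisible(path)
}
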