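#' Raw differential-expression score between two cell groups
#'
#' Every cell of group A is compared against every cell of group B
#' (`n1 x n2` ordered pairs). For each pair and gene, the noise model yields
#' a two-sided p-value for the observed fold-change; the signed
#' `-log10 p` values (positive when the gene is higher in A) are summed into
#' the per-gene raw score. The computation groups the zero entries
#' algebraically and is identical to full pair enumeration.
#'
#' @param expr A normalized `expression_matrix`.
#' @param cells_a,cells_b Disjoint cell index vectors (positions or names),
#'   each of size >= 2.
#' @param model A `noise_model`.
#' @return List with `raw` (per-gene raw score) and `eff` (per-gene
#'   effective number of comparisons: pairs where the gene is detected in at
#'   least one of the two cells).
#' @export
raw_de_score <- function(expr, cells_a, cells_b, model) {
  cells_a <- resolve_cells(expr, cells_a)
  cells_b <- resolve_cells(expr, cells_b)
  if (length(intersect(cells_a, cells_b)))
    stop("cell groups overlap")
  if (length(cells_a) < 2 || length(cells_b) < 2)
    stop("both groups need >= 2 cells")
  xa <- Matrix::t(expr$counts[, cells_a, drop = FALSE])  # cells x genes
  xb <- Matrix::t(expr$counts[, cells_b, drop = FALSE])
  out <- raw_score_sparse(xa@x, xa@p, length(cells_a),
                          xb@x, xb@p, length(cells_b),
                          length(expr$genes),
                          model$breaks, unlist(model$nulls), model$offsets,
                          model$pseudocount)
  out$raw <- stats::setNames(out$raw, expr$genes)
  out$eff <- stats::setNames(out$eff, expr$genes)
  out
}

resolve_cells <- function(expr, cells) {
  if (is.character(cells)) cells <- match(cells, expr$cells)
  if (anyNA(cells)) stop("unknown cell identifier")
  as.integer(cells)
}

#' Reference (brute-force) raw score
#'
#' Exact O(n1 * n2) pair enumeration through [lfc_pvalue()]; the grouped
#' implementation in [raw_de_score()] must agree with this to 1e-9.
#'
#' @inheritParams raw_de_score
#' @return Named per-gene numeric vector.
#' @export
raw_de_score_ref <- function(expr, cells_a, cells_b, model) {
  cells_a <- resolve_cells(expr, cells_a)
  cells_b <- resolve_cells(expr, cells_b)
  A <- as.matrix(expr$counts[, cells_a, drop = FALSE])
  B <- as.matrix(expr$counts[, cells_b, drop = FALSE])
  out <- numeric(nrow(A))
  for (g in seq_len(nrow(A))) {
    s <- 0
    for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
      a <- A[g, i]; b <- B[g, j]
      if (a == b) next
      p <- lfc_pvalue(model, a, b)
      s <- s + sign(log2(a + model$pseudocount) -
                    log2(b + model$pseudocount)) * (-log10(p))
    }
    out[g] <- s
  }
  stats::setNames(out, expr$genes)
}

#' Adjust raw scores into numerical-model Z-scores
#'
#' The null distribution of the raw score is estimated by reshuffling the
#' pooled cells of the two groups into random groups of the same sizes and
#' recomputing the score (`reshuffles` times, default 3). The per-gene null
#' mean is the mean of the reshuffled scores; the null standard deviation is
#' pooled across genes as `c * m_g`, linear in the gene's effective number
#' of comparisons `m_g`, with an inflation factor `sqrt(1 + 1/R)` because
#' the null mean is itself estimated from R reshuffles, and a floor `eps`.
#'
#' @inheritParams raw_de_score
#' @param reshuffles Number of random label permutations (>= 1, default 3).
#' @param eps Floor on the null standard deviation (default 1e-8).
#' @param raw Optional precomputed result of [raw_de_score()].
#' @return List with `z_num`, `raw`, `eff`, `null_mean`, `null_sd`.
#' @export
adjust_raw_score <- function(expr, cells_a, cells_b, model, reshuffles = 3,
                             eps = 1e-8, raw = NULL) {
  if (reshuffles < 1) stop("reshuffles must be >= 1")
  if (is.null(raw)) raw <- raw_de_score(expr, cells_a, cells_b, model)
  cells_a <- resolve_cells(expr, cells_a)
  cells_b <- resolve_cells(expr, cells_b)
  pool <- c(cells_a, cells_b)
  n1 <- length(cells_a)
  nullmat <- matrix(0, length(expr$genes), reshuffles)
  for (r in seq_len(reshuffles)) {
    perm <- sample(pool)
    nullmat[, r] <- raw_de_score(expr, perm[seq_len(n1)], perm[-seq_len(n1)],
                                 model)$raw
  }
  null_mean <- rowMeans(nullmat)
  m <- raw$eff
  ok <- m > 0
  if (reshuffles >= 2) {
    dev <- (nullmat[ok, , drop = FALSE] - null_mean[ok]) / m[ok]
    c_hat <- sqrt(sum(dev^2) / (sum(ok) * (reshuffles - 1)))
  } else {
    c_hat <- sqrt(mean((nullmat[ok, 1] / m[ok])^2))
  }
  c_hat <- c_hat * sqrt(1 + 1 / reshuffles)
  null_sd <- pmax(eps, c_hat * m)
  z <- (raw$raw - null_mean) / null_sd
  z[!ok] <- 0
  list(z_num = stats::setNames(z, expr$genes), raw = raw$raw, eff = m,
       null_mean = null_mean, null_sd = null_sd)
}

#' Wilcoxon rank-sum Z-scores per gene
#'
#' Signed normal approximation of the Mann-Whitney U statistic with tie
#' correction and continuity correction; positive when group A is
#' stochastically larger.
#'
#' @inheritParams raw_de_score
#' @return Named per-gene numeric vector of Z-scores.
#' @export
wilcoxon_z <- function(expr, cells_a, cells_b) {
  cells_a <- resolve_cells(expr, cells_a)
  cells_b <- resolve_cells(expr, cells_b)
  if (length(cells_a) < 2 || length(cells_b) < 2)
    stop("both groups need >= 2 cells")
  n1 <- length(cells_a); n2 <- length(cells_b)
  X <- as.matrix(expr$counts[, c(cells_a, cells_b), drop = FALSE])
  n <- n1 + n2
  mu <- n1 * n2 / 2
  z <- apply(X, 1, function(v) {
    r <- rank(v)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    t <- rle(sort(v))$lengths
    tie <- sum(t^3 - t)
    s2 <- n1 * n2 / 12 * ((n + 1) - tie / (n * (n - 1)))
    if (s2 <= 0) return(0)
    d <- U - mu
    if (d == 0) return(0)
    (d - 0.5 * sign(d)) / sqrt(s2)
  })
  stats::setNames(z, expr$genes)
}

#' Merge the two Z-scores
#'
#' The magnitude is the modulus of the two-dimensional vector,
#' `sqrt(Z_num^2 + Z_wilcoxon^2)` — rewarding genes scored high by both
#' tests — and the sign is taken from `z_num`, falling back to `z_wilcoxon`
#' when `z_num` is zero.
#'
#' @param z_num Numerical-model Z-scores.
#' @param z_wilcoxon Wilcoxon Z-scores (same gene order).
#' @return Signed final Z-scores.
#' @export
merge_z <- function(z_num, z_wilcoxon) {
  if (length(z_num) != length(z_wilcoxon))
    stop("Z-score vectors have different lengths")
  s <- sign(z_num)
  s[s == 0] <- sign(z_wilcoxon)[s == 0]
  s[s == 0] <- 1   # both zero: magnitude is zero anyway
  s * sqrt(z_num^2 + z_wilcoxon^2)
}

#' Z-score matrix over all cluster pairs
#'
#' For `x` clusters runs the full DE scoring over all `x * (x - 1) / 2`
#' unique cluster pairs (lexicographic order over sorted cluster labels,
#' i < j); each comparison yields a final signed Z-score per gene. Clusters
#' with fewer than 2 cells are merged into the nearest cluster by centroid
#' (Pearson on log expression) with a warning.
#'
#' @param expr A normalized `expression_matrix` (typically restricted to
#'   expressed genes).
#' @param clustering Cell cluster labels: vector along cells, or a
#'   `cluster_tree` from [recursive_cluster()].
#' @param model A `noise_model`; fitted on `expr` when `NULL`.
#' @param reshuffles Label permutations for the numerical null (default 3).
#' @return A `zscore_matrix`: `z` (genes x comparisons matrix of final
#'   Z-scores), `z_num`, `z_wilcoxon` (same shape), `comparisons` (tibble
#'   with cluster_a, cluster_b, n1, n2), `clusters` (final labels).
#' @export
zscore_matrix <- function(expr, clustering, model = NULL, reshuffles = 3) {
  labels <- if (inherits(clustering, "cluster_tree"))
    clustering$assignments else clustering
  if (length(labels) != length(expr$cells))
    stop("one cluster label per cell required")
  labels <- as.character(labels)
  labels <- merge_small_clusters(expr, labels, min_cells = 2)
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("need >= 2 clusters")
  if (is.null(model)) model <- fit_noise_model(expr)
  pairs <- utils::combn(length(cl), 2)
  K <- ncol(pairs)
  G <- length(expr$genes)
  Z <- Zn <- Zw <- matrix(0, G, K, dimnames = list(expr$genes, NULL))
  comp <- vector("list", K)
  for (k in seq_len(K)) {
    ca <- which(labels == cl[pairs[1, k]])
    cb <- which(labels == cl[pairs[2, k]])
    adj <- adjust_raw_score(expr, ca, cb, model, reshuffles = reshuffles)
    zw <- wilcoxon_z(expr, ca, cb)
    Zn[, k] <- adj$z_num
    Zw[, k] <- zw
    Z[, k] <- merge_z(adj$z_num, zw)
    comp[[k]] <- tibble::tibble(cluster_a = cl[pairs[1, k]],
                                cluster_b = cl[pairs[2, k]],
                                n1 = length(ca), n2 = length(cb))
  }
  comp <- dplyr::bind_rows(comp)
  colnames(Z) <- colnames(Zn) <- colnames(Zw) <-
    paste0(comp$cluster_a, "_vs_", comp$cluster_b)
  structure(list(z = Z, z_num = Zn, z_wilcoxon = Zw,
                 comparisons = comp, clusters = labels),
            class = "zscore_matrix")
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat(sprintf("zscore_matrix: %d genes x %d cluster-pair comparisons (%d clusters)\n",
              nrow(x$z), ncol(x$z), length(unique(x$clusters))))
  invisible(x)
}

#' Write a Z-score matrix as TSV (genes x named comparisons)
#' @param x A `zscore_matrix`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_zscores <- function(x, path) {
  utils::write.table(data.frame(gene = rownames(x$z), x$z, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

merge_small_clusters <- function(expr, labels, min_cells = 2) {
  repeat {
    sizes <- table(labels)
    small <- names(sizes)[sizes < min_cells]
    if (length(small) == 0 || length(sizes) <= 1) return(labels)
    warning("cluster '", small[1], "' has < ", min_cells,
            " cells; merged into nearest cluster by centroid")
    cent <- vapply(names(sizes), function(l)
      log2(Matrix::rowMeans(expr$counts[, labels == l, drop = FALSE]) +
             expr$pseudocount),
      numeric(length(expr$genes)))
    d <- 1 - stats::cor(cent)
    diag(d) <- Inf
    target <- names(sizes)[which.min(d[small[1], ])]
    labels[labels == small[1]] <- target
  }
}
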