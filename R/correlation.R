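#' Gene-gene correlations in Z-score space
#'
#' Computes Pearson, Spearman and Cosine coefficients between the Z-score
#' profiles of every retained gene pair (genes as vectors over the
#' cluster-pair comparisons). Genes with zero variance across comparisons
#' are excluded.
#'
#' @param z A `zscore_matrix` or a genes x comparisons numeric matrix with
#'   at least 3 columns.
#' @param genes_mask Optional logical/character/integer gene subset.
#' @return A `correlation_table` tibble: `gene1`, `gene2`
#'   (`gene1 < gene2` lexicographically), `rho_p`, `rho_s`, `rho_c`,
#'   `rho_combined`; attribute `genes` holds the retained gene order.
#' @export
correlate_zspace <- function(z, genes_mask = NULL) {
  Z <- if (inherits(z, "zscore_matrix")) z$z else as.matrix(z)
  if (ncol(Z) < 3)
    stop("insufficient cluster structure: need >= 3 comparison columns")
  if (!is.null(genes_mask)) Z <- Z[genes_mask, , drop = FALSE]
  v <- apply(Z, 1, stats::var)
  Z <- Z[v > 0, , drop = FALSE]
  if (nrow(Z) < 2) stop("fewer than 2 genes with variable Z profiles")
  mats <- zspace_cor_matrices(Z)
  idx <- which(upper.tri(mats$p), arr.ind = TRUE)
  g <- rownames(Z)
  swap <- g[idx[, 1]] > g[idx[, 2]]
  out <- tibble::tibble(
    gene1 = ifelse(swap, g[idx[, 2]], g[idx[, 1]]),
    gene2 = ifelse(swap, g[idx[, 1]], g[idx[, 2]]),
    rho_p = mats$p[idx],
    rho_s = mats$s[idx],
    rho_c = mats$c[idx]
  )
  out$rho_combined <- combine_worst(out$rho_p, out$rho_c)
  attr(out, "genes") <- g
  class(out) <- c("correlation_table", class(out))
  out
}

# Dense coefficient matrices over gene rows of Z.
zspace_cor_matrices <- function(Z) {
  tz <- t(Z)
  p <- stats::cor(tz)
  s <- stats::cor(tz, method = "spearman")
  nrm <- sqrt(rowSums(Z^2))
  zn <- Z / nrm
  co <- tcrossprod(zn)
  list(p = p, s = s, c = co)
}

#' Combine Pearson and Cosine conservatively
#'
#' The combined coefficient is the worst (smallest-magnitude) of the two
#' when they agree in sign, keeping the shared sign; a sign conflict yields
#' 0 (the "worst" of two coefficients of opposite sign is not defined, and
#' zero is the conservative reading).
#'
#' @param rho_p,rho_c Pearson and Cosine coefficients (vectorized).
#' @return Combined coefficients.
#' @export
combine_worst <- function(rho_p, rho_c) {
  out <- sign(rho_p) * pmin(abs(rho_p), abs(rho_c))
  out[sign(rho_p) * sign(rho_c) < 0] <- 0
  out[is.na(rho_p) | is.na(rho_c)] <- NA_real_
  out
}

#' Adaptive correlation threshold
#'
#' Keeps the top `fraction` (default 0.1%) of candidate pairs by
#' `|rho_combined|`; the threshold actually applied, `rho_thresh`, is the
#' magnitude of the k-th largest combined coefficient (`k =
#' ceiling(fraction * P)`), and boundary ties are all kept. This relative
#' rule equalizes datasets of different size and depth.
#'
#' @param tab A `correlation_table`.
#' @param fraction Fraction of pairs to retain (default 0.001).
#' @return `tab` with columns `rho_thresh` and `kept` added.
#' @export
adaptive_threshold <- function(tab, fraction = 0.001) {
  P <- nrow(tab)
  if (P == 0) stop("no candidate pairs")
  k <- ceiling(fraction * P)
  mag <- abs(tab$rho_combined)
  thresh <- sort(mag, decreasing = TRUE)[k]
  tab$rho_thresh <- thresh
  tab$kept <- mag >= thresh
  tab
}

#' Spearman control on kept pairs
#'
#' Kept pairs whose Spearman coefficient is weak relative to the adaptive
#' threshold — `|rho_s| < |rho_thresh - 0.15|` — are considered null and
#' dropped.
#'
#' @param tab A `correlation_table` after [adaptive_threshold()].
#' @param margin Spearman margin below the threshold (default 0.15).
#' @return `tab` with `kept` updated.
#' @export
spearman_control <- function(tab, margin = 0.15) {
  if (is.null(tab$rho_thresh)) stop("run adaptive_threshold() first")
  bound <- abs(tab$rho_thresh - margin)
  tab$kept <- tab$kept & !(abs(tab$rho_s) < bound)
  tab
}

#' Z-space correlation pipeline
#'
#' [correlate_zspace()], [adaptive_threshold()] and [spearman_control()] in
#' sequence: the complete path from a Z-score matrix to flagged candidate
#' edges.
#'
#' @inheritParams correlate_zspace
#' @inheritParams adaptive_threshold
#' @inheritParams spearman_control
#' @return A `correlation_table` with `rho_thresh` and `kept`.
#' @export
zscore_correlations <- function(z, genes_mask = NULL, fraction = 0.001,
                                margin = 0.15) {
  tab <- correlate_zspace(z, genes_mask)
  tab <- adaptive_threshold(tab, fraction)
  spearman_control(tab, margin)
}

#' Write candidate edges as TSV
#' @param tab A `correlation_table`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_correlations <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
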