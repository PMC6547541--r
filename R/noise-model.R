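#' Fit the numerical noise model
#'
#' Cells with highly similar transcriptomes are treated as biological
#' replicates and grouped greedily; the expression variation between cells of
#' the same group is then the estimator of technical noise. Concretely, the
#' log2 fold-changes among all within-group cell pairs are binned by the log2
#' mean expression of the pair, giving a per-bin empirical null against which
#' any observed fold-change is assigned a two-sided p-value (add-one
#' smoothed, so p is never 0 and p equals 1 at fold-change 0).
#'
#' @param expr A normalized `expression_matrix` with at least 20 cells.
#' @param n_top_genes Number of highly expressed genes used for the cell-cell
#'   rank (Spearman) similarity (default 200).
#' @param sim_quantile Quantile of the off-diagonal similarity distribution a
#'   candidate group must exceed (default 0.90: "top 10% most mutually
#'   similar cells").
#' @param group_size Target pseudo-replicate group size (default 5, the
#'   minimum for a valid group).
#' @param max_groups Cap on the number of groups (default 20).
#' @param n_bins Number of expression-level bins on the log2 mean (default 15).
#' @return A `noise_model`: bin breaks, per-bin sorted null |lfc| values,
#'   pseudo-replicate group membership, pseudocount.
#' @export
fit_noise_model <- function(expr, n_top_genes = 200, sim_quantile = 0.90,
                            group_size = 5, max_groups = 20, n_bins = 15) {
  stopifnot(inherits(expr, "expression_matrix"))
  n <- length(expr$cells)
  if (n < 20) stop("need >= 20 cells to fit the noise model")
  if (!expr$normalized)
    stop("fit the noise model on a normalized matrix (see normalize_counts())")

  means <- Matrix::rowMeans(expr$counts)
  top <- utils::head(order(means, decreasing = TRUE), n_top_genes)
  le <- log_expr(expr, genes = top)
  sim <- suppressWarnings(stats::cor(le, method = "spearman"))
  sim[is.na(sim)] <- -1   # zero-variance cells: never grouped
  diag(sim) <- NA
  tau <- stats::quantile(sim, sim_quantile, na.rm = TRUE, names = FALSE)

  groups <- greedy_replicate_groups(sim, tau, group_size, max_groups)
  if (length(groups) == 0)
    stop("no pseudo-replicate group could be formed at this similarity ",
         "level; use noise_model_poisson() as a fallback null")

  build_noise_model(expr, groups, n_bins)
}

# Greedy grouping: seed with the most mutually similar unused pair, grow by
# the unused cell with highest mean similarity to the group while that mean
# stays above tau; groups smaller than `size` are discarded.
greedy_replicate_groups <- function(sim, tau, size, max_groups) {
  n <- nrow(sim)
  used <- logical(n)
  groups <- list()
  while (length(groups) < max_groups) {
    s <- sim
    s[used, ] <- NA; s[, used] <- NA
    if (all(is.na(s))) break
    best <- which(s == max(s, na.rm = TRUE), arr.ind = TRUE)[1, ]
    if (s[best[1], best[2]] < tau) break
    grp <- as.integer(best)
    repeat {
      cand <- which(!used & !(seq_len(n) %in% grp))
      if (length(cand) == 0 || length(grp) >= size) break
      ms <- colMeans(sim[grp, cand, drop = FALSE], na.rm = TRUE)
      j <- cand[which.max(ms)]
      if (max(ms) < tau) break
      grp <- c(grp, j)
    }
    if (length(grp) >= size) {
      groups[[length(groups) + 1]] <- grp
      used[grp] <- TRUE
    } else {
      # seed pair unusable; block it so the loop advances
      used[best[1]] <- TRUE
    }
  }
  groups
}

build_noise_model <- function(expr, groups, n_bins, pairs = NULL) {
  pc <- expr$pseudocount
  lm_all <- numeric(0); alfc_all <- numeric(0)
  if (is.null(pairs)) {
    for (grp in groups) {
      le <- log2(as.matrix(expr$counts[, grp, drop = FALSE]) + pc)
      idx <- utils::combn(length(grp), 2)
      for (k in seq_len(ncol(idx))) {
        a <- le[, idx[1, k]]; b <- le[, idx[2, k]]
        keep <- a != log2(pc) | b != log2(pc)   # drop undetected-in-both pairs
        lm_all <- c(lm_all, (a[keep] + b[keep]) / 2)
        alfc_all <- c(alfc_all, abs(a[keep] - b[keep]))
      }
    }
  } else {
    lm_all <- pairs$logmean; alfc_all <- pairs$alfc
  }
  if (length(lm_all) < 10 * n_bins)
    n_bins <- max(1L, length(lm_all) %/% 10L)
  breaks <- unique(stats::quantile(lm_all, probs = seq_len(n_bins - 1) / n_bins,
                                   names = FALSE))
  bin <- findInterval(lm_all, breaks) + 1L
  n_bins <- length(breaks) + 1L
  nulls <- lapply(seq_len(n_bins), function(k) sort(alfc_all[bin == k]))
  structure(
    list(breaks = breaks,
         nulls = nulls,
         offsets = c(0L, cumsum(lengths(nulls))),
         pseudocount = pc,
         groups = groups,
         n_null = length(alfc_all)),
    class = "noise_model"
  )
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("noise_model: %d bins, %d null fold-changes, %d replicate group(s)\n",
              length(x$nulls), x$n_null, length(x$groups)))
  invisible(x)
}

#' Poisson fallback noise model
#'
#' For datasets too small or heterogeneous for pseudo-replicate grouping: the
#' null log-fold-change distribution is generated by drawing Poisson pairs at
#' each gene's mean normalized expression, emulating pure counting noise.
#'
#' @param expr A normalized `expression_matrix`.
#' @param n_pairs Simulated null pairs per gene (default 20).
#' @param n_bins Expression-level bins (default 15).
#' @return A `noise_model`.
#' @export
noise_model_poisson <- function(expr, n_pairs = 20, n_bins = 15) {
  pc <- expr$pseudocount
  mu <- Matrix::rowMeans(expr$counts)
  mu <- mu[mu > 0]
  a <- stats::rpois(length(mu) * n_pairs, rep(mu, n_pairs))
  b <- stats::rpois(length(mu) * n_pairs, rep(mu, n_pairs))
  la <- log2(a + pc); lb <- log2(b + pc)
  keep <- a != 0 | b != 0
  build_noise_model(expr, groups = list(), n_bins = n_bins,
                    pairs = list(logmean = (la[keep] + lb[keep]) / 2,
                                 alfc = abs(la[keep] - lb[keep])))
}

#' Two-sided p-value of an expression change under the noise model
#'
#' Vectorized over pairs of (normalized) expression values. `p = 1` whenever
#' the two values are equal; within a bin, p is non-increasing in the
#' absolute log fold-change; the smoothing floor is `1/(N_bin + 1)`.
#'
#' @param model A `noise_model`.
#' @param a,b Expression values (recycled to common length).
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
lfc_pvalue <- function(model, a, b) {
  la <- log2(a + model$pseudocount)
  lb <- log2(b + model$pseudocount)
  alfc <- abs(la - lb)
  bin <- findInterval((la + lb) / 2, model$breaks) + 1L
  p <- numeric(length(alfc))
  for (k in unique(bin)) {
    i <- bin == k
    nb <- model$nulls[[k]]
    # findInterval(left.open = TRUE) counts null values strictly below the
    # observation, so n_ge includes ties (two-sided tail with >=)
    n_ge <- length(nb) - findInterval(alfc[i], nb, left.open = TRUE)
    p[i] <- (1 + n_ge) / (length(nb) + 1)
  }
  p
}
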