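#' Add mean-dependent dropout to an existing count matrix
#'
#' Bernoulli thinning with keep-probability logistic in the entry's log
#' expression (the observed count stands in for the underlying mean;
#' lowly expressed transcripts drop out more), with the intercept
#' calibrated by bisection so the realized overall zero fraction lands
#' within +/-1% of `target_sparsity`. Used to degrade a near-dense
#' reference to a benchmark sparsity level.
#'
#' @param expr An `expression_matrix` of raw counts.
#' @param target_sparsity Desired zero fraction in `[0, 1)`.
#' @param shape Logistic slope (default 1).
#' @param mode `"logistic"` (default) or `"uniform"`.
#' @return A degraded `expression_matrix`.
#' @export
add_dropout <- function(expr, target_sparsity, shape = 1,
                        mode = c("logistic", "uniform")) {
  mode <- match.arg(mode)
  counts <- as.matrix(expr$counts)
  if (sparsity(expr) > target_sparsity + 0.01)
    stop(sprintf("matrix already sparser (%.3f) than target %.3f",
                 sparsity(expr), target_sparsity))
  out <- apply_dropout(counts, counts, target_sparsity, shape, mode)
  expression_matrix(out, genes = expr$genes, cells = expr$cells,
                    pseudocount = expr$pseudocount)
}

#' Run the Z-score correlation pipeline on raw counts
#'
#' Normalization, expressed-gene masking, noise-model fit, recursive
#' clustering, Z-score matrix over all cluster pairs, and Z-space
#' correlations with the adaptive threshold and Spearman control. This is
#' the shared engine behind [infer_grn()] and the benchmark harness.
#'
#' @param expr An `expression_matrix` of raw counts.
#' @param min_cells Expressed-gene mask: minimum detecting cells (default 5).
#' @param fraction Adaptive-threshold fraction (default 0.001).
#' @param reshuffles DE null permutations (default 3).
#' @param min_size,max_depth,n_hvg Clustering controls (see
#'   [recursive_cluster()]).
#' @param clustering Optional precomputed labels (skips clustering).
#' @param margin Spearman control margin (default 0.15).
#' @return List: `expr` (normalized, masked), `clustering`, `model`, `z`
#'   (`zscore_matrix`), `corr` (`correlation_table`).
#' @export
zscore_pipeline <- function(expr, min_cells = 5, fraction = 0.001,
                            reshuffles = 3, min_size = NULL, max_depth = 6,
                            n_hvg = 500, clustering = NULL, margin = 0.15) {
  e <- normalize_counts(expr)
  mask <- expressed_genes(e, min_cells)
  e <- e[mask, ]
  ct <- clustering
  if (is.null(ct)) {
    ct <- recursive_cluster(e, min_size = min_size, max_depth = max_depth,
                            n_hvg = n_hvg)
    # the correlation stage needs >= 3 cluster-pair comparisons; on a very
    # degraded matrix the tree may stop at 2 leaves, so retry once at a
    # finer partition size before giving up
    if (length(unique(ct$assignments)) < 3) {
      finer <- max(10L, (if (is.null(min_size))
        (if (length(e$cells) < 5000) 50L else ceiling(length(e$cells) / 100))
        else min_size) %/% 2L)
      ct2 <- recursive_cluster(e, min_size = finer, max_depth = max_depth,
                               n_hvg = n_hvg)
      if (length(unique(ct2$assignments)) > length(unique(ct$assignments)))
        ct <- ct2
    }
  }
  model <- fit_noise_model(e)
  zm <- zscore_matrix(e, ct, model, reshuffles = reshuffles)
  tab <- zscore_correlations(zm, fraction = fraction, margin = margin)
  list(expr = e, clustering = ct, model = model, z = zm, corr = tab)
}

#' AUC of true-correlation recovery on degraded data
#'
#' Runs the Z-score pipeline on a degraded matrix and scores every
#' candidate pair by its absolute combined correlation; the ROC is taken
#' against membership in the reference truth set (pairs with
#' `|Pearson| > 0.8` on the near-dense reference) over all evaluable pairs,
#' and the AUC is computed by the rank (Mann-Whitney) identity, which
#' equals the trapezoidal area under the ROC curve.
#'
#' @param truth A `sim_truth` (from [simulate_counts()]) or a tibble with
#'   `gene1`, `gene2`.
#' @param degraded An `expression_matrix` sharing the truth's gene space.
#' @param ... Passed to [zscore_pipeline()].
#' @return List: `auc`, `n_pos`, `n_pairs`, `n_clusters`.
#' @export
auc_recovery <- function(truth, degraded, ...) {
  pairs <- if (inherits(truth, "sim_truth")) truth$true_pairs else truth
  if (nrow(pairs) == 0) stop("empty truth set")
  run <- zscore_pipeline(degraded, ...)
  tab <- run$corr
  lab <- paste(tab$gene1, tab$gene2) %in% paste(pairs$gene1, pairs$gene2)
  list(auc = rank_auc(abs(tab$rho_combined), lab),
       n_pos = sum(lab), n_pairs = nrow(tab),
       n_clusters = length(unique(run$z$clusters)))
}

#' AUC by the rank identity
#'
#' `AUC = (U / (n_pos * n_neg))` with U the Mann-Whitney statistic of the
#' positive-class scores (midranks for ties); identical to the trapezoidal
#' area under the ROC curve.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Logical class labels.
#' @return Scalar AUC.
#' @export
rank_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Dropout-recovery benchmark over seeds and sparsity levels
#'
#' For each seed: simulate a near-dense (3% sparsity) reference with
#' planted modules, define the truth as its `|Pearson| > 0.8` pairs,
#' degrade to each target sparsity with mean-dependent dropout, run the
#' full pipeline and record the recovery AUC.
#'
#' @param sparsities Target zero fractions (default `c(0.88, 0.97)`).
#' @param seeds Simulation seeds (default 1:10).
#' @param config Generator configuration (default [sim_config()] with
#'   `target_sparsity = 0.03`).
#' @param ... Passed to [zscore_pipeline()].
#' @return Tibble `sparsity`, `seed`, `auc`, `n_pos`, `n_pairs`,
#'   `n_clusters`.
#' @export
benchmark_dropout_auc <- function(sparsities = c(0.88, 0.97), seeds = 1:10,
                                  config = sim_config(target_sparsity = 0.03),
                                  ...) {
  purrr::map_dfr(seeds, function(s) {
    sim <- simulate_counts(config, seed = s)
    truth <- reference_true_pairs(sim$expr)
    purrr::map_dfr(sparsities, function(sp) {
      set.seed(s + 104729L)   # dropout + pipeline stream, separate from sim
      deg <- add_dropout(sim$expr, sp)
      res <- auc_recovery(truth, deg, ...)
      tibble::tibble(sparsity = sp, seed = s, auc = res$auc,
                     n_pos = res$n_pos, n_pairs = res$n_pairs,
                     n_clusters = res$n_clusters)
    })
  })
}

#' False discovery rate under random cluster assignment
#'
#' Any correlation recovered after randomly permuting cells into clusters
#' of the same sizes must be a false positive. Per repetition: permute the
#' cells, rebuild the Z-score matrix and correlations, and count pairs
#' whose absolute combined correlation passes the supplied (real-data)
#' threshold; FDR is passed/candidates.
#'
#' @param expr A raw `expression_matrix`.
#' @param cluster_sizes Integer cluster sizes to preserve (e.g. from the
#'   real clustering).
#' @param rho_thresh The real-data adaptive threshold to apply.
#' @param n_reps Repetitions (default 5).
#' @param reshuffles DE null permutations per comparison (default 3).
#' @param min_cells Expressed-gene mask (default 5).
#' @return List: `fdr_mean`, `fdr_sem`, `per_rep` tibble.
#' @export
null_fdr <- function(expr, cluster_sizes, rho_thresh, n_reps = 5,
                     reshuffles = 3, min_cells = 5) {
  stopifnot(sum(cluster_sizes) == length(expr$cells))
  e <- normalize_counts(expr)
  e <- e[expressed_genes(e, min_cells), ]
  model <- fit_noise_model(e)
  per <- purrr::map_dfr(seq_len(n_reps), function(r) {
    labels <- sample(rep(seq_along(cluster_sizes), times = cluster_sizes))
    stopifnot(identical(sort(as.integer(table(labels))),
                        sort(as.integer(cluster_sizes))))
    zm <- zscore_matrix(e, labels, model, reshuffles = reshuffles)
    tab <- correlate_zspace(zm)
    tibble::tibble(rep = r,
                   candidates = nrow(tab),
                   passed = sum(abs(tab$rho_combined) >= rho_thresh),
                   fdr = .data$passed / .data$candidates)
  })
  list(fdr_mean = mean(per$fdr),
       fdr_sem = stats::sd(per$fdr) / sqrt(n_reps),
       per_rep = per)
}

#' Train/test reproducibility of inferred correlations
#'
#' Splits the cells into two disjoint halves, runs the full pipeline
#' independently on each, and reports — among training pairs whose combined
#' correlation exceeds `rho_train` — the fraction whose test correlation
#' exceeds each level in `rho_tests`, next to the background rate over all
#' common pairs.
#'
#' @param expr A raw `expression_matrix`.
#' @param split_seed Seed for the random half split.
#' @param rho_train Training selection level (default 0.8).
#' @param rho_tests Test levels (default `c(0.8, 0.6)`).
#' @param ... Passed to [zscore_pipeline()].
#' @return Tibble `rho_test`, `n_selected`, `fraction`, `background`.
#' @export
train_test_prediction <- function(expr, split_seed = 1, rho_train = 0.8,
                                  rho_tests = c(0.8, 0.6), ...) {
  n <- length(expr$cells)
  if (n < 8) stop("halves too small to cluster")
  set.seed(split_seed)
  idx <- sample(n)
  half1 <- sort(idx[seq_len(n %/% 2)])
  half2 <- sort(idx[(n %/% 2 + 1):n])
  r1 <- zscore_pipeline(expr[, half1], ...)
  r2 <- zscore_pipeline(expr[, half2], ...)
  common <- dplyr::inner_join(
    tibble::as_tibble(r1$corr)[, c("gene1", "gene2", "rho_combined")],
    tibble::as_tibble(r2$corr)[, c("gene1", "gene2", "rho_combined")],
    by = c("gene1", "gene2"), suffix = c("_train", "_test"))
  selected <- common[common$rho_combined_train > rho_train, , drop = FALSE]
  purrr::map_dfr(rho_tests, function(rt) tibble::tibble(
    rho_test = rt,
    n_selected = nrow(selected),
    fraction = if (nrow(selected)) mean(selected$rho_combined_test > rt)
    else NA_real_,
    background = mean(common$rho_combined_test > rt)))
}
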