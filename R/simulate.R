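#' Simulation configuration
#'
#' Defaults define the reference benchmark conditions: 2000 genes, 1000
#' cells in 5 clusters, gamma-distributed gene means (shape 2, scale 12), negative-binomial
#' counts with moderate overdispersion, 10% of genes differentially
#' expressed per cluster at 4-fold effect, ten planted co-regulated modules
#' of ten genes sharing a cluster profile (the source of true positive
#' correlations), and a near-dense reference at 3% sparsity.
#'
#' @param n_genes,n_cells,n_clusters Dimensions of the dataset.
#' @param cluster_proportions Mixing proportions (default equal; must sum
#'   to 1).
#' @param mean_shape,mean_scale Gamma hyper-parameters for baseline gene
#'   means (default shape 2, scale 12).
#' @param dispersion NB dispersion (1/size; default 0.3).
#' @param de_prob Fraction of genes differentially expressed per cluster
#'   (default 0.1, the field's customary simulation default).
#' @param de_fold Fold-change of DE genes (default 4; up or down with equal
#'   probability).
#' @param n_modules,module_size Planted co-regulated modules: groups of
#'   genes sharing one cluster profile (default 10 modules of 10 genes).
#' @param target_sparsity Overall zero fraction after dropout, in `[0, 1)`;
#'   NA applies no dropout beyond the baseline (default NA).
#' @param dropout_shape Slope of the logistic mean-dependent dropout in
#'   log-mean (default 1); `dropout_mode = "uniform"` ignores the mean.
#' @param dropout_mode `"logistic"` (default) or `"uniform"`.
#' @param lib_sd Log-normal sd of per-cell library size factors (default
#'   0.25).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, n_cells = 1000, n_clusters = 5,
                       cluster_proportions = NULL,
                       mean_shape = 2, mean_scale = 12,
                       dispersion = 0.3, de_prob = 0.1, de_fold = 4,
                       n_modules = 10, module_size = 10,
                       target_sparsity = NA, dropout_shape = 1,
                       dropout_mode = c("logistic", "uniform"),
                       lib_sd = 0.25) {
  dropout_mode <- match.arg(dropout_mode)
  if (is.null(cluster_proportions))
    cluster_proportions <- rep(1 / n_clusters, n_clusters)
  stopifnot(abs(sum(cluster_proportions) - 1) < 1e-8,
            is.na(target_sparsity) ||
              (target_sparsity >= 0 && target_sparsity < 1))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate clustered scRNA-seq counts with planted correlation structure
#'
#' Splat-style hierarchy: baseline gene means are gamma draws; each cluster
#' multiplies a random subset of genes (fraction `de_prob`) by `de_fold` or
#' its inverse; genes of a planted module share one cluster profile so that
#' their reference expression is correlated by construction; cells get
#' log-normal library factors; counts are negative binomial. Dropout is
#' applied as Bernoulli thinning with keep-probability logistic in the
#' log-mean (low-expression genes drop out more), calibrated by bisection
#' on the intercept so the realized zero fraction is within +/-1% of
#' `target_sparsity`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (deterministic output).
#' @return List: `expr` (raw `expression_matrix` after dropout), `truth`
#'   (a `sim_truth`: `reference` expression_matrix before dropout,
#'   `true_pairs` tibble of gene pairs with `|Pearson| > 0.8` on the
#'   log-scaled reference, `clusters`, `modules`).
#' @export
simulate_counts <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  G <- config$n_genes; N <- config$n_cells; K <- config$n_clusters
  cnt <- diff(c(0, round(cumsum(config$cluster_proportions) * N)))
  clusters <- sample(rep(seq_len(K), times = cnt))
  base_mu <- stats::rgamma(G, shape = config$mean_shape,
                           scale = config$mean_scale)
  # per-gene x cluster fold factors
  lf <- matrix(0, G, K)
  for (k in seq_len(K)) {
    de <- which(stats::runif(G) < config$de_prob)
    lf[de, k] <- sample(c(1, -1), length(de), replace = TRUE) *
      log(config$de_fold)
  }
  # planted modules: members share the profile of the module's first gene
  modules <- list()
  if (config$n_modules > 0) {
    pool <- sample.int(G, config$n_modules * config$module_size)
    for (m in seq_len(config$n_modules)) {
      mem <- pool[((m - 1) * config$module_size + 1):(m * config$module_size)]
      prof <- sample(c(1, -1), K, replace = TRUE) * log(config$de_fold)
      lf[mem, ] <- matrix(prof, length(mem), K, byrow = TRUE)
      modules[[m]] <- mem
    }
  }
  lib <- exp(stats::rnorm(N, 0, config$lib_sd))
  mu <- (base_mu * exp(lf[, clusters])) * rep(lib, each = G)
  size <- 1 / config$dispersion
  counts <- matrix(stats::rnbinom(G * N, mu = mu, size = size), G, N)
  reference <- expression_matrix(counts)
  ref_sparsity <- sparsity(reference)

  if (!is.na(config$target_sparsity)) {
    if (ref_sparsity > config$target_sparsity + 0.01)
      stop(sprintf("baseline already sparser (%.3f) than target %.3f",
                   ref_sparsity, config$target_sparsity))
    counts <- apply_dropout(counts, mu, config$target_sparsity,
                            config$dropout_shape, config$dropout_mode)
  }
  expr <- expression_matrix(counts)

  truth <- structure(
    list(reference = reference,
         true_pairs = reference_true_pairs(reference),
         clusters = clusters, modules = modules),
    class = "sim_truth")
  list(expr = expr, truth = truth)
}

# Bernoulli thinning; keep-probability logistic in the entry's underlying
# log mean expression (lowly expressed transcripts drop out more, and a
# gene's detection rate tracks its true expression in each cell), with the
# intercept calibrated by bisection to the target overall zero fraction.
# With unit slope this is the Michaelis-Menten detection curve
# keep_p = mu / (mu + M).
apply_dropout <- function(counts, mu, target, shape, mode) {
  G <- nrow(counts); N <- ncol(counts)
  lmu <- log(mu + 1e-8)   # entry-level (gene x cell) underlying means
  u <- matrix(stats::runif(G * N), G, N)
  keep_of <- function(x0) {
    if (mode == "logistic") 1 / (1 + exp(-shape * (lmu - x0)))
    else max(0, min(1, 1 - x0))
  }
  realized <- function(x0) mean(counts * (u < keep_of(x0)) == 0)
  lo <- if (mode == "logistic") min(lmu) - 40 else 0
  hi <- if (mode == "logistic") max(lmu) + 40 else 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (realized(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  x0 <- (lo + hi) / 2
  if (abs(realized(x0) - target) > 0.01)
    stop(sprintf("dropout calibration failed: realized %.3f vs target %.3f",
                 realized(x0), target))
  counts * (u < keep_of(x0))
}

# gene pairs with |Pearson| > 0.8 on log2(count + 1) of the reference
reference_true_pairs <- function(reference, cutoff = 0.8) {
  le <- log2(as.matrix(reference$counts) + 1)
  v <- apply(le, 1, stats::var)
  keep <- which(v > 0)
  cc <- stats::cor(t(le[keep, , drop = FALSE]))
  idx <- which(abs(cc) > cutoff & upper.tri(cc), arr.ind = TRUE)
  g <- reference$genes[keep]
  tibble::tibble(gene1 = pmin(g[idx[, 1]], g[idx[, 2]]),
                 gene2 = pmax(g[idx[, 1]], g[idx[, 2]]),
                 rho_ref = cc[idx])
}

#' Jaccard co-expression of a gene pair
#'
#' Fraction of cells detecting both genes among cells detecting either.
#'
#' @param expr An `expression_matrix`.
#' @param gene1,gene2 Gene identifiers or indices.
#' @return Scalar in `[0, 1]` (0 when the union is empty).
#' @export
coexpression_jaccard <- function(expr, gene1, gene2) {
  a <- as.numeric(expr$counts[gene1, ]) != 0
  b <- as.numeric(expr$counts[gene2, ]) != 0
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Jaccard co-expression for a table of pairs
#'
#' @param expr An `expression_matrix`.
#' @param pairs Tibble with `gene1`, `gene2`.
#' @return `pairs` with a `jaccard` column.
#' @export
pairs_jaccard <- function(expr, pairs) {
  det <- as.matrix(expr$counts[unique(c(pairs$gene1, pairs$gene2)), ,
                               drop = FALSE] != 0)
  pairs$jaccard <- purrr::map2_dbl(pairs$gene1, pairs$gene2, function(g1, g2) {
    u <- sum(det[g1, ] | det[g2, ])
    if (u == 0) 0 else sum(det[g1, ] & det[g2, ]) / u
  })
  pairs
}
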