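# brute-force coefficient oracles, independent of the implementation
oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}
oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))
oracle_cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

test_that("coefficients equal brute-force oracles on random fixtures", {
  set.seed(101)
  Z <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(paste0("g", 1:5), NULL))
  tab <- correlate_zspace(Z)
  expect_equal(nrow(tab), 10L)
  for (r in seq_len(nrow(tab))) {
    x <- Z[tab$gene1[r], ]; y <- Z[tab$gene2[r], ]
    expect_equal(tab$rho_p[r], oracle_pearson(x, y), tolerance = 1e-12)
    expect_equal(tab$rho_s[r], oracle_spearman(x, y), tolerance = 1e-12)
    expect_equal(tab$rho_c[r], oracle_cosine(x, y), tolerance = 1e-12)
  }
})

test_that("duplicated and negated genes hit the coefficient extremes", {
  set.seed(5)
  z <- rnorm(8)
  Z <- rbind(a = z, b = z, c = -z)
  tab <- correlate_zspace(Z)
  ab <- tab[tab$gene1 == "a" & tab$gene2 == "b", ]
  expect_equal(c(ab$rho_p, ab$rho_s, ab$rho_c), c(1, 1, 1), tolerance = 1e-12)
  ac <- tab[tab$gene1 == "a" & tab$gene2 == "c", ]
  expect_equal(c(ac$rho_p, ac$rho_s), c(-1, -1), tolerance = 1e-12)
})

test_that("zero-variance genes are excluded; few columns are an error", {
  Z <- rbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4), c = c(2, 1, 4, 3))
  tab <- correlate_zspace(Z)
  expect_false("a" %in% c(tab$gene1, tab$gene2))
  expect_error(correlate_zspace(Z[, 1:2]), "insufficient cluster structure")
})

test_that("pearson/spearman are invariant to positive affine maps, cosine is not", {
  set.seed(7)
  Z <- matrix(rnorm(4 * 8), 4, 8, dimnames = list(paste0("g", 1:4), NULL))
  Z2 <- Z
  Z2[2, ] <- 3 * Z[2, ] + 1    # positive-slope affine on one gene
  t1 <- correlate_zspace(Z); t2 <- correlate_zspace(Z2)
  r12 <- function(t) t[t$gene1 == "g1" & t$gene2 == "g2", ]
  expect_equal(r12(t1)$rho_p, r12(t2)$rho_p, tolerance = 1e-12)
  expect_equal(r12(t1)$rho_s, r12(t2)$rho_s, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(r12(t1)$rho_c, r12(t2)$rho_c,
                                tolerance = 1e-6)))
})

test_that("worst-of combination keeps the shared sign, zeroes conflicts", {
  expect_equal(combine_worst(0.9, 0.85), 0.85)
  expect_equal(combine_worst(-0.9, -0.95), -0.9)
  expect_equal(combine_worst(0.9, -0.2), 0)
  expect_equal(combine_worst(-0.1, 0.9), 0)
  expect_equal(combine_worst(c(0.5, -0.5), c(0.4, -0.6)), c(0.4, -0.5))
})

test_that("adaptive threshold keeps ceil(fraction * P) pairs plus ties", {
  set.seed(11)
  P <- 10000
  tab <- tibble::tibble(
    gene1 = sprintf("a%05d", 1:P), gene2 = sprintf("b%05d", 1:P),
    rho_p = NA, rho_s = runif(P, -1, 1), rho_c = NA,
    rho_combined = sample(seq(0, 1, length.out = P)))
  out <- adaptive_threshold(tab, fraction = 0.001)
  expect_equal(sum(out$kept), 10L)
  expect_equal(out$rho_thresh[1], sort(abs(out$rho_combined),
                                       decreasing = TRUE)[10])
  # all magnitudes equal: everything is a boundary tie and is kept
  tab$rho_combined <- 0.5
  expect_true(all(adaptive_threshold(tab, 0.001)$kept))
  expect_error(adaptive_threshold(tab[0, ], 0.001), "no candidate")
})

test_that("spearman control removes weak-rank pairs at the stated bound", {
  tab <- tibble::tibble(gene1 = c("a", "a", "b"), gene2 = c("b", "c", "c"),
                        rho_p = 1, rho_c = 1,
                        rho_s = c(0.60, 0.80, -0.10),
                        rho_combined = c(0.95, 0.93, 0.92),
                        rho_thresh = 0.90, kept = TRUE)
  out <- spearman_control(tab)
  expect_equal(out$kept, c(FALSE, TRUE, FALSE))   # bound = 0.75
  # threshold at the margin: bound 0 removes nothing
  tab$rho_thresh <- 0.15
  expect_true(all(spearman_control(tab)$kept))
})

test_that("kept set is a deterministic function of the Z matrix", {
  set.seed(13)
  Z <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(paste0("g", 1:60), NULL))
  a <- zscore_correlations(Z, fraction = 0.01)
  b <- zscore_correlations(Z, fraction = 0.01)
  expect_identical(a, b)
})

test_that("Z-space exposes dropout-hidden module correlations", {
  # two co-regulated modules at 85% dropout: count-space pearson misses
  # them, Z-space recovers far more strong pairs
  set.seed(404)
  cfg <- sim_config(n_genes = 500, n_cells = 400, n_clusters = 4,
                    n_modules = 4, module_size = 8,
                    target_sparsity = 0.85)
  sim <- simulate_counts(cfg, seed = 404)
  e <- normalize_counts(sim$expr)
  e <- e[expressed_genes(e), ]
  le <- log2(as.matrix(e$counts) + 1)
  v <- apply(le, 1, var)
  cc <- suppressWarnings(cor(t(le[v > 0, ])))
  n_counts <- sum(abs(cc[upper.tri(cc)]) > 0.8, na.rm = TRUE)
  set.seed(1)
  run <- zscore_pipeline(sim$expr, min_size = 40)
  n_z <- sum(abs(run$corr$rho_p) > 0.8)
  expect_gte(n_z, 10 * max(1, n_counts))
})
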