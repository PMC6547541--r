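test_that("noise-model p-values are 1 at zero change, floored, symmetric", {
  e <- normalize_counts(null_counts(seed = 5))
  set.seed(2)
  m <- fit_noise_model(e)
  expect_equal(lfc_pvalue(m, 7, 7), 1)
  expect_equal(lfc_pvalue(m, 0, 0), 1)
  # far beyond any null sample: smoothing floor 1/(N_bin+1)
  nbin <- lengths(m$nulls)
  pfloor <- lfc_pvalue(m, 1e6, 0)
  k <- findInterval((log2(1e6 + 1) + log2(1)) / 2, m$breaks) + 1
  expect_equal(pfloor, 1 / (nbin[k] + 1))
  # symmetry p(a,b) == p(b,a) on a grid of generated pairs
  set.seed(7)
  a <- rpois(200, 10); b <- rpois(200, 10)
  expect_equal(lfc_pvalue(m, a, b), lfc_pvalue(m, b, a), tolerance = 1e-12)
  # monotone non-increasing in |lfc| within a bin: fix geometric mean
  g <- 20
  ratios <- 2^seq(0, 4, by = 0.5)
  ps <- lfc_pvalue(m, g * sqrt(ratios), g / sqrt(ratios))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("poisson fallback model is available for tiny datasets", {
  e <- normalize_counts(null_counts(n_cells = 10, seed = 3))
  expect_error(fit_noise_model(e), ">= 20 cells")
  set.seed(1)
  m <- noise_model_poisson(e)
  expect_s3_class(m, "noise_model")
  expect_equal(lfc_pvalue(m, 4, 4), 1)
})

test_that("grouped raw score equals brute-force pair enumeration", {
  set.seed(11)
  e <- normalize_counts(expression_matrix(matrix(rpois(15 * 12, 5), 15, 12)))
  m <- poisson_model(e)
  fast <- raw_de_score(e, 1:6, 7:12, m)
  slow <- raw_de_score_ref(e, 1:6, 7:12, m)
  expect_equal(fast$raw, slow, tolerance = 1e-9)
  # effective comparisons: pairs with detection in >= 1 of the two cells
  A <- as.matrix(e$counts[, 1:6]); B <- as.matrix(e$counts[, 7:12])
  eff <- sapply(seq_len(15), function(g) 36 - sum(A[g, ] == 0) * sum(B[g, ] == 0))
  expect_equal(unname(fast$eff), eff)
})

test_that("raw score is antisymmetric, zero for silent genes, rejects overlap", {
  set.seed(12)
  cnt <- matrix(rpois(10 * 10, 4), 10, 10)
  cnt[3, ] <- 0
  e <- normalize_counts(expression_matrix(cnt))
  m <- poisson_model(e)
  ab <- raw_de_score(e, 1:5, 6:10, m)
  ba <- raw_de_score(e, 6:10, 1:5, m)
  expect_equal(ab$raw, -ba$raw, tolerance = 1e-12)
  expect_equal(unname(ab$raw[3]), 0)
  expect_error(raw_de_score(e, 1:5, 5:10, m), "overlap")
  expect_error(raw_de_score(e, 1, 2:5, m), ">= 2 cells")
})

test_that("raw score arithmetic: constant p and sign sum as expected", {
  # all 6 pairs upregulated with p = 0.01 -> raw = 6 * 2
  # constructed via a degenerate one-bin model whose null makes p(lo,hi)=0.01
  e <- expression_matrix(matrix(c(8, 8, 2, 2, 2), 1, 5))
  e$normalized <- TRUE
  lfc <- abs(log2(9 / 3))
  model <- structure(list(
    breaks = numeric(0),
    nulls = list(c(rep(0, 99), lfc)),   # N = 100: p at lfc = (1+1)/101? no:
    offsets = c(0L, 100L),
    pseudocount = 1, groups = list(), n_null = 100), class = "noise_model")
  # choose null so that ties give exactly p = 0.01: 100 values < lfc, none >=
  model$nulls <- list(sort(runif(99, 0, lfc / 2)))
  model$offsets <- c(0L, 99L)
  p <- lfc_pvalue(model, 8, 2)
  expect_equal(p, 1 / 100)
  rs <- raw_de_score(e, 1:2, 3:5, model)
  expect_equal(unname(rs$raw), 6 * 2)
})

test_that("numerical-model Z is centered by the reshuffle null", {
  set.seed(21)
  e <- normalize_counts(null_counts(n_genes = 200, n_cells = 60, seed = 21))
  m <- poisson_model(e)
  adj <- adjust_raw_score(e, 1:30, 31:60, m, reshuffles = 3)
  # raw equal to the null mean implies Z exactly 0
  z0 <- (adj$null_mean - adj$null_mean) / adj$null_sd
  expect_equal(unname(z0), rep(0, 200))
  # scale invariance of the standardization
  expect_equal((2 * (adj$raw - adj$null_mean)) / (2 * adj$null_sd),
               (adj$raw - adj$null_mean) / adj$null_sd)
  expect_error(adjust_raw_score(e, 1:30, 31:60, m, reshuffles = 0), ">= 1")
})

test_that("planted 4-fold DE gene exceeds the null Z distribution", {
  set.seed(31)
  n <- 40
  mu <- rgamma(150, 2, scale = 6)
  cnt1 <- matrix(rpois(150 * n, mu), 150, n)
  mu2 <- mu; mu2[1:5] <- mu2[1:5] * 4
  cnt2 <- matrix(rpois(150 * n, mu2), 150, n)
  e <- normalize_counts(expression_matrix(cbind(cnt1, cnt2)))
  m <- fit_noise_model(e)
  adj <- adjust_raw_score(e, 1:n, (n + 1):(2 * n), m)
  planted <- abs(adj$z_num[1:5])
  others <- abs(adj$z_num[-(1:5)])
  expect_true(all(planted > quantile(others, 0.95)))
})

test_that("wilcoxon Z matches the closed form and is antisymmetric", {
  e <- expression_matrix(matrix(c(11:20, 1:10), nrow = 1))
  # n1 = n2 = 10, complete separation, no ties: U = 100,
  # Z = (100 - 50 - 0.5)/sqrt(175) with continuity correction
  expect_equal(unname(wilcoxon_z(e, 1:10, 11:20)), 49.5 / sqrt(175))
  expect_equal(wilcoxon_z(e, 1:10, 11:20), -wilcoxon_z(e, 11:20, 1:10))
  # identical multisets give Z = 0
  e2 <- expression_matrix(matrix(c(1, 2, 3, 1, 2, 3), 1))
  expect_equal(unname(wilcoxon_z(e2, 1:3, 4:6)), 0)
})

test_that("merge_z takes the modulus with the numerical-model sign", {
  expect_equal(merge_z(3, 4), 5)
  expect_equal(merge_z(-3, -4), -5)
  expect_equal(merge_z(-3, 4), -5)
  expect_equal(merge_z(0, -2), -2)
  expect_equal(merge_z(0, 0), 0)
  expect_error(merge_z(1:3, 1:2), "length")
  # merged magnitude dominates both components
  set.seed(1)
  zn <- rnorm(50); zw <- rnorm(50)
  zf <- merge_z(zn, zw)
  expect_true(all(abs(zf) >= pmax(abs(zn), abs(zw)) - 1e-12))
})

test_that("zscore_matrix yields x(x-1)/2 lexicographic comparisons", {
  set.seed(41)
  e <- normalize_counts(null_counts(n_genes = 120, n_cells = 60, seed = 41))
  m <- poisson_model(e)
  zm <- zscore_matrix(e, rep(1:3, each = 20), m)
  expect_equal(ncol(zm$z), 3L)
  expect_equal(colnames(zm$z), c("1_vs_2", "1_vs_3", "2_vs_3"))
  zm4 <- zscore_matrix(e, rep(1:4, each = 15), m)
  expect_equal(ncol(zm4$z), 6L)
  expect_error(zscore_matrix(e, rep(1, 60), m), ">= 2 clusters")
  # a 1-cell cluster is merged away with a warning
  labels <- c(rep(1, 30), rep(2, 29), 3)
  expect_warning(zm3 <- zscore_matrix(e, labels, m), "merged")
  expect_equal(ncol(zm3$z), 1L)
})

test_that("same-cluster halves score lower than cross-cluster comparisons", {
  set.seed(51)
  fix <- two_pop_counts(n_genes = 150, n_per = 40, n_markers = 25, seed = 51)
  e <- normalize_counts(fix$expr)
  m <- fit_noise_model(e)
  # split each true population randomly in half -> 4 pseudo-clusters
  labels <- fix$labels * 10 + sample(0:1, 80, replace = TRUE)
  zm <- zscore_matrix(e, labels, m)
  same <- c("10_vs_11", "20_vs_21")
  cross <- setdiff(colnames(zm$z), same)
  planted <- fix$markers
  same_max <- max(abs(zm$z[planted, same]))
  cross_min_top <- min(apply(abs(zm$z[planted, cross, drop = FALSE]), 2, max))
  expect_gt(cross_min_top, same_max)
})

test_that("null Z-scores are calibrated and components are z-like", {
  set.seed(61)
  mu <- exp(rnorm(600, 1, 1.3))
  cnt <- matrix(rpois(600 * 400, mu), 600, 400)
  e <- normalize_counts(expression_matrix(cnt))
  e <- e[expressed_genes(e), ]
  m <- fit_noise_model(e)
  labels <- sample(rep(1:4, each = 100))
  zm <- zscore_matrix(e, labels, m)
  expect_lt(abs(mean(zm$z)), 0.1)
  expect_gt(sd(zm$z), 0.7)
  # the merge formula fixes E[Z^2] = E[Zn^2] + E[Zw^2] (= 2 when both are
  # unit), so the merged sd concentrates near sqrt(2)
  expect_lt(sd(zm$z), sqrt(2) + 0.1)
  expect_gt(sd(zm$z_num), 0.7);      expect_lt(sd(zm$z_num), 1.4)
  expect_gt(sd(zm$z_wilcoxon), 0.7); expect_lt(sd(zm$z_wilcoxon), 1.4)
})
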