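test_that("HVG ranking surfaces variable genes and signals termination", {
  # constant genes only: termination signal (empty set)
  e <- expression_matrix(matrix(5, 50, 30))
  e$normalized <- TRUE
  expect_length(highly_variable_genes(e), 0)

  # one gene with much higher CV than all others at equal mean ranks first
  set.seed(2)
  base <- matrix(rpois(60 * 40, 20), 60, 40)
  spike <- rep(c(0, 40), each = 20)      # mean 20, huge CV
  m2 <- rbind(spike, base)
  rownames(m2) <- NULL
  e2 <- expression_matrix(m2)
  e2$normalized <- TRUE
  hv <- highly_variable_genes(e2, n_hvg = 10)
  expect_equal(hv[1], e2$genes[1])
})

test_that("HVG finds planted markers in a two-population mixture", {
  set.seed(9)
  mu <- rgamma(400, 2, scale = 8)
  lf <- rep(1, 400)
  lf[1:30] <- 8; lf[31:60] <- 1 / 8   # markers move in both directions
  m1 <- matrix(rpois(400 * 100, mu), 400, 100)
  m2 <- matrix(rpois(400 * 100, mu * lf), 400, 100)
  e <- normalize_counts(expression_matrix(cbind(m1, m2)))
  top50 <- highly_variable_genes(e, n_hvg = 50)
  frac <- mean(top50 %in% e$genes[1:60])
  expect_gt(frac, 0.8)
})

test_that("the two-increases cut rule follows the stated sequences", {
  # increases at levels 4 and 5 -> cut at level 3
  expect_equal(choose_cut_level(c(2, 2, 2, 3, 4, 5, 6, 7, 8)), 3L)
  # no increase at all -> fallback at the median level
  expect_equal(choose_cut_level(rep(1L, 9)), 5L)
  # single isolated increase -> fallback
  expect_equal(choose_cut_level(c(1, 2, 2, 2, 2, 2, 2, 2, 2)), 5L)
  # first increase at 2, but first *consecutive* pair at (4, 5) -> cut at 3
  expect_equal(choose_cut_level(c(1, 2, 2, 3, 4, 4, 4, 4, 4)), 3L)
  # increases from the very start -> cut at 1
  expect_equal(choose_cut_level(c(2, 3, 4, 4, 4, 4, 4, 4, 4)), 1L)
})

test_that("cut_tree_elbow counts clusters at the nine decile levels", {
  set.seed(4)
  x <- c(rnorm(20, 0), rnorm(20, 10))
  hc <- hclust(dist(x), method = "ward.D2")
  cut <- cut_tree_elbow(hc)
  expect_length(cut$counts, 9)
  expect_true(all(diff(cut$counts) >= 0))   # deeper level, never fewer
  expect_true(all(cut$labels[1:20] == cut$labels[1]))
})

test_that("small homogeneous data yields one cluster, no recursion", {
  e <- normalize_counts(null_counts(n_genes = 150, n_cells = 40, seed = 6))
  ct <- recursive_cluster(e, min_size = 50)
  expect_equal(length(unique(ct$assignments)), 1L)
})

test_that("two well-separated populations give two pure leaves", {
  fix <- two_pop_counts(n_genes = 300, n_per = 100, n_markers = 40,
                        fold = 8, seed = 13)
  e <- normalize_counts(fix$expr)
  ct <- recursive_cluster(e, min_size = 50)
  expect_equal(length(unique(ct$assignments)), 2L)
  purity <- max(table(ct$assignments, fix$labels)[, 1]) /
    sum(fix$labels == 1)
  expect_gte(purity, 0.98)
})

test_that("nested populations are segregated into three leaves", {
  set.seed(17)
  n <- 80
  mu <- rgamma(300, 2, scale = 8)
  big <- matrix(rpois(300 * n, mu), 300, n)            # population A
  muB <- mu; muB[1:40] <- muB[1:40] * 8                # B differs strongly
  b1 <- matrix(rpois(300 * n, muB), 300, n)
  muB2 <- muB; muB2[41:70] <- muB2[41:70] * 6          # B sub-population
  b2 <- matrix(rpois(300 * n, muB2), 300, n)
  e <- normalize_counts(expression_matrix(cbind(big, b1, b2)))
  ct <- recursive_cluster(e, min_size = 40)
  truth <- rep(1:3, each = n)
  expect_equal(length(unique(ct$assignments)), 3L)
  agree <- table(ct$assignments, truth)
  expect_gte(sum(apply(agree, 1, max)) / length(truth), 0.95)
})

test_that("partition, determinism and min_size monotonicity hold", {
  fix <- two_pop_counts(n_genes = 250, n_per = 80, n_markers = 30, seed = 23)
  e <- normalize_counts(fix$expr)
  ct1 <- recursive_cluster(e, min_size = 40)
  # leaves partition all cells
  expect_false(anyNA(ct1$assignments))
  expect_equal(length(ct1$assignments), length(e$cells))
  # determinism (no RNG inside)
  ct2 <- recursive_cluster(e, min_size = 40)
  expect_identical(ct1$assignments, ct2$assignments)
  # lowering min_size never decreases the number of leaves
  ct3 <- recursive_cluster(e, min_size = 20)
  expect_gte(length(unique(ct3$assignments)),
             length(unique(ct1$assignments)))
})

test_that("assignments round-trip as TSV and the tree serializes", {
  fix <- two_pop_counts(seed = 29)
  e <- normalize_counts(fix$expr)
  ct <- recursive_cluster(e, min_size = 30)
  td <- withr::local_tempdir()
  write_clusters(ct, file.path(td, "cl.tsv"), file.path(td, "tree.json"))
  back <- read.delim(file.path(td, "cl.tsv"))
  expect_equal(back$cluster, unname(ct$assignments))
  expect_true(jsonlite::validate(paste(readLines(file.path(td, "tree.json")),
                                       collapse = "")))
})
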