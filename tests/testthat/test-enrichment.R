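mk_sets <- function(n_sets, genes, p_member, seed = 1) {
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i)
    genes[runif(length(genes)) < p_member])
  names(sets) <- paste0("S", seq_len(n_sets))
  gene_set_collection(sets[lengths(sets) > 0])
}

test_that("edge co-occurrence fold and p follow the 2x2 construction", {
  # S = 100 signatures; g1 in 50, g2 in 50, both in 25 -> independence
  sets <- lapply(1:100, function(i) {
    s <- character(0)
    if (i <= 50) s <- c(s, "g1")
    if (i > 25 && i <= 75) s <- c(s, "g2")
    c(s, "filler")
  })
  names(sets) <- paste0("S", 1:100)
  gs <- gene_set_collection(sets)
  net <- igraph::make_graph(~ g1 - g2)
  res <- edge_cooccurrence(net, gs)
  expect_equal(res$a, 25); expect_equal(res$d, 25)
  expect_equal(res$fold, 1)

  # complete overlap: fold 2, p equals the hypergeometric point mass
  sets2 <- lapply(1:100, function(i)
    if (i <= 50) c("g1", "g2") else "filler")
  names(sets2) <- paste0("S", 1:100)
  res2 <- edge_cooccurrence(net, gene_set_collection(sets2))
  expect_equal(res2$fold, 2)
  expect_equal(res2$p, 1 / choose(100, 50), tolerance = 1e-12)

  # a = 0 with positive margins: fold 0, p = 1
  sets3 <- lapply(1:100, function(i)
    if (i <= 50) "g1" else "g2")
  names(sets3) <- paste0("S", 1:100)
  res3 <- edge_cooccurrence(net, gene_set_collection(sets3))
  expect_equal(res3$fold, 0)
  expect_equal(res3$p, 1)
  expect_error(edge_cooccurrence(net, gene_set_collection(list())), "empty")
})

test_that("edge p equals the exact hypergeometric tail across 2x2 tables", {
  # sweep margins for several signature totals S <= 200
  for (S in c(20, 57, 200)) for (m1 in c(3, S %/% 3)) for (m2 in c(5, S %/% 2)) {
    for (a in unique(c(0, 1, min(m1, m2) %/% 2, min(m1, m2)))) {
      sets <- lapply(seq_len(S), function(i) {
        s <- "filler"
        if (i <= a) s <- c(s, "x", "y")
        else if (i <= m1) s <- c(s, "x")
        else if (i <= m1 + (m2 - a)) s <- c(s, "y")
        s
      })
      names(sets) <- paste0("S", seq_len(S))
      res <- edge_cooccurrence(igraph::make_graph(~ x - y),
                               gene_set_collection(sets))
      # oracle: upper tail of the hypergeometric by direct summation
      kmax <- min(m1, m2)
      probs <- sapply(a:kmax, function(k)
        choose(m2, k) * choose(S - m2, m1 - k) / choose(S, m1))
      expect_equal(res$p, sum(probs), tolerance = 1e-10)
    }
  }
})

test_that("ES follows the log-odds formula with permutation p", {
  ess <- tibble::tibble(gene = paste0("g", 1:9000),
                        essential = rep(c(TRUE, FALSE, FALSE), 3000))
  # equal hub and background fractions -> ES = 0
  hubs0 <- paste0("g", 1:30)    # pattern T,F,F matches background odds
  set.seed(3)
  r0 <- essentiality_score(hubs0, ess, n_perm = 500)
  expect_equal(r0$es, 0)
  expect_gt(r0$p_empirical, 0.2)

  # direct arithmetic: (30, 10) hubs vs (3000, 6000) background -> log2 6
  ess2 <- tibble::tibble(gene = paste0("h", 1:9000),
                         essential = rep(c(TRUE, FALSE), c(3000, 6000)))
  hubs2 <- paste0("h", c(1:30, 3001:3010))
  set.seed(4)
  r2 <- essentiality_score(hubs2, ess2, n_perm = 2000)
  expect_equal(r2$e_hubs, 30); expect_equal(r2$ne_hubs, 10)
  expect_equal(r2$es, log2(6), tolerance = 1e-12)
  expect_lt(r2$p_empirical, 0.01)
  expect_gte(r2$p_empirical, 1 / 2001)

  # hubs = whole catalogue -> ES = 0 and p near 1
  set.seed(5)
  rall <- essentiality_score(ess2$gene, ess2, n_perm = 200)
  expect_equal(rall$es, 0)
  expect_gt(rall$p_empirical, 0.3)
})

test_that("permutation p is reproducible and converges with n_perm", {
  ess <- tibble::tibble(gene = paste0("g", 1:2000),
                        essential = rep(c(TRUE, FALSE), c(500, 1500)))
  hubs <- paste0("g", c(1:40, 501:520))   # enriched set
  set.seed(11); p1 <- essentiality_score(hubs, ess, n_perm = 2000)$p_empirical
  set.seed(11); p1b <- essentiality_score(hubs, ess, n_perm = 2000)$p_empirical
  expect_identical(p1, p1b)
  set.seed(12); p2 <- essentiality_score(hubs, ess, n_perm = 4000)$p_empirical
  se <- sqrt(p1 * (1 - p1) / 2000)
  expect_lt(abs(p2 - p1), 3 * se + 1e-6)
})

test_that("BH correction is applied across hub sets", {
  ess <- tibble::tibble(gene = paste0("g", 1:1000),
                        essential = rep(c(TRUE, FALSE), c(300, 700)))
  sets <- list(a = paste0("g", 1:50), b = paste0("g", 301:350),
               c = paste0("g", sample(1000, 50)))
  set.seed(21)
  out <- essentiality_scores(sets, ess, n_perm = 500)
  expect_equal(out$p_adjusted, p.adjust(out$p_empirical, "BH"))
})

test_that("organ specificity: exclusivity and expression multiplicity", {
  mk_tab <- function(vals) {
    tibble::tibble(node = paste0("g", seq_along(vals)), degree = vals,
                   betweenness = vals, closeness = vals,
                   pagerank = vals, eigenvector = vals)
  }
  # g1 top in organ A only; g2 top in both organs
  ta <- mk_tab(c(10, 9, 1, 1, 1, 1, 1, 1, 1, 1))
  tb <- mk_tab(c(1, 9, 10, 1, 1, 1, 1, 1, 1, 1))
  means <- cbind(A = c(10, 1, 2, 1, 1), B = c(1, 1, 10, 1, 1),
                 C = c(2, 1, 1, 1, 1), D = c(1, 1, 2, 1, 1),
                 E = c(3, 1, 3, 1, 1))
  rownames(means) <- paste0("g", 1:5)
  res <- organ_specificity(list(A = ta, B = tb), means, metric = "pagerank")
  g1 <- res[res$gene == "g1", ]; g2 <- res[res$gene == "g2", ]
  expect_true(g1$exclusive); expect_equal(g1$centrality_multiplicity, 1L)
  expect_equal(g2$centrality_multiplicity, 2L); expect_false(g2$exclusive)
  # constant organ means: IQR (type 7) = 0 -> flagged, Z treated as 0
  expect_true(res$iqr_zero[res$gene == "g4"])
  expect_equal(res$expression_multiplicity[res$gene == "g4"], 0)
  # quartile oracle under the type-7 convention for g1 = (10,1,2,1,3):
  x <- c(10, 1, 2, 1, 3)
  iqr <- unname(quantile(x, 0.75, type = 7) - quantile(x, 0.25, type = 7))
  z <- (x - median(x)) / iqr
  expect_equal(res$expression_multiplicity[res$gene == "g1"], sum(z > 2))
  expect_error(organ_specificity(list(A = ta), means), ">= 2 organs")
})

test_that("organ-label permutation permutes centrality membership", {
  set.seed(31)
  tabs <- lapply(1:3, function(i) {
    v <- runif(20)
    tibble::tibble(node = paste0("g", 1:20), degree = v, betweenness = v,
                   closeness = v, pagerank = v, eigenvector = v)
  })
  names(tabs) <- c("X", "Y", "Z")
  means <- matrix(runif(60), 20, 3,
                  dimnames = list(paste0("g", 1:20), c("X", "Y", "Z")))
  r1 <- organ_specificity(tabs, means)
  perm <- c("Y", "Z", "X")
  r2 <- organ_specificity(setNames(tabs, perm), means[, perm][, c(3,1,2)])
  # multiplicities are invariant under a consistent relabeling
  expect_equal(r1$centrality_multiplicity, r2$centrality_multiplicity)
})

test_that("hypergeometric enrichment matches combinatorial arithmetic", {
  universe <- paste0("u", 1:20)
  sets <- list(hit = universe[1:10], miss = universe[11:14])
  query <- universe[1:5]
  out <- hypergeom_enrichment(query, sets, universe)
  # P(all 5 draws inside the 10-gene set) = C(10,5)/C(20,5)
  expect_equal(out$p[out$set == "hit"], choose(10, 5) / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(out$p[out$set == "miss"], 1)
  expect_equal(out$p_bonferroni, pmin(1, out$p * 2))
  expect_lt(out$p[1], out$p[2])   # ordering: exact-match set first
  expect_error(hypergeom_enrichment(query, sets, character(0)), "empty")
  expect_error(hypergeom_enrichment("zz", sets, universe), "inside")
})
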