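#' Per-edge gene-set co-occurrence test
#'
#' For each network edge, builds the 2x2 table of signatures containing
#' both endpoint genes (a), only the first (b), only the second (c), or
#' neither (d), over all evaluable signatures `S = a+b+c+d`, and computes
#' the fold enrichment of co-occurrence `a*S / ((a+b)(a+c))` together with a
#' one-sided (enrichment) Fisher exact p-value — equivalently the
#' hypergeometric upper tail. Edges whose genes are missing from the
#' collection universe are skipped and counted.
#'
#' @param net An `igraph` network.
#' @param sets A `gene_set_collection` (e.g. from [read_gmt()]).
#' @param alternative `"greater"` (default, enrichment) or `"two.sided"`.
#' @param case_insensitive Match gene identifiers case-insensitively at this
#'   boundary (default TRUE; mouse vs human symbol capitalization).
#' @return A tibble `gene1`, `gene2`, `a`, `b`, `c`, `d`, `fold`, `p`;
#'   attributes `n_skipped` (edges with out-of-universe genes) and
#'   `frac_validated` (fraction of tested edges with p < 0.05).
#' @export
edge_cooccurrence <- function(net, sets, alternative = c("greater", "two.sided"),
                              case_insensitive = TRUE) {
  alternative <- match.arg(alternative)
  if (length(sets$sets) == 0) stop("empty gene-set collection")
  uni <- sets$universe
  key <- if (case_insensitive) toupper else identity
  memb <- matrix(FALSE, length(uni), length(sets$sets),
                 dimnames = list(key(uni), names(sets$sets)))
  for (j in seq_along(sets$sets))
    memb[key(sets$sets[[j]]), j] <- TRUE
  el <- igraph::as_data_frame(net, what = "edges")[, 1:2]
  names(el) <- c("gene1", "gene2")
  i1 <- match(key(el$gene1), rownames(memb))
  i2 <- match(key(el$gene2), rownames(memb))
  ok <- !is.na(i1) & !is.na(i2)
  S <- ncol(memb)
  res <- purrr::map_dfr(which(ok), function(e) {
    m1 <- memb[i1[e], ]; m2 <- memb[i2[e], ]
    a <- sum(m1 & m2); b <- sum(m1 & !m2); c <- sum(!m1 & m2)
    d <- S - a - b - c
    fold <- if ((a + b) > 0 && (a + c) > 0)
      a * S / ((a + b) * (a + c)) else NA_real_
    p <- if (alternative == "greater")
      stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
    else stats::fisher.test(matrix(c(a, b, c, d), 2),
                            alternative = "two.sided")$p.value
    tibble::tibble(gene1 = el$gene1[e], gene2 = el$gene2[e],
                   a = a, b = b, c = c, d = d, fold = fold, p = p)
  })
  attr(res, "n_skipped") <- sum(!ok)
  attr(res, "frac_validated") <- if (nrow(res)) mean(res$p < 0.05) else NA_real_
  res
}

#' Fraction of validated edges by minimum signature occurrence
#'
#' The validation curve: restricting to edges whose genes appear in at
#' least `min_occ` signatures (both margins), what fraction reach p < 0.05?
#'
#' @param cooc Result of [edge_cooccurrence()].
#' @param min_occ Vector of minimum-occurrence cutoffs.
#' @return Tibble `min_occ`, `n_edges`, `frac_validated`.
#' @export
validation_curve <- function(cooc, min_occ = c(0, 5, 10, 20, 50, 100)) {
  purrr::map_dfr(min_occ, function(k) {
    sub <- cooc[(cooc$a + cooc$b) >= k & (cooc$a + cooc$c) >= k, ]
    tibble::tibble(min_occ = k, n_edges = nrow(sub),
                   frac_validated = if (nrow(sub)) mean(sub$p < 0.05)
                   else NA_real_)
  })
}

#' Essentiality score of a hub set with permutation p-value
#'
#' `ES = log2((E_hubs/NE_hubs) / (E_bg/NE_bg))`: the log2 ratio of the
#' essential-to-nonessential odds among the hubs versus the background
#' catalogue. Significance is the one-tailed empirical probability that a
#' random same-size draw from the background reaches an ES at least as
#' large, over `n_perm` draws with add-one smoothing.
#'
#' @param hubs Character vector of hub genes.
#' @param ess Essentiality tibble (`gene`, `essential`), e.g. from
#'   [read_essentiality()].
#' @param n_perm Permutation draws (default 10000).
#' @param case_insensitive Case-fold gene matching (default TRUE).
#' @return One-row tibble: `n_hubs` (hubs found in the catalogue),
#'   `e_hubs`, `ne_hubs`, `e_bg`, `ne_bg`, `es`, `es_haldane` (+0.5 on all
#'   counts; finite when a count is zero), `p_empirical`.
#' @export
essentiality_score <- function(hubs, ess, n_perm = 10000,
                               case_insensitive = TRUE) {
  if (!all(c("gene", "essential") %in% names(ess)))
    stop("essentiality table needs columns gene, essential")
  stopifnot(any(ess$essential), any(!ess$essential))
  idx <- if (case_insensitive) match_genes_ci(hubs, ess$gene)
  else match(hubs, ess$gene)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) stop("no hub gene found in the essentiality catalogue")
  is_e <- ess$essential
  e_bg <- sum(is_e); ne_bg <- sum(!is_e)
  e_h <- sum(is_e[idx]); ne_h <- length(idx) - e_h
  es_of <- function(e, ne) log2((e / ne) / (e_bg / ne_bg))
  es <- es_of(e_h, ne_h)
  es_hald <- log2(((e_h + 0.5) / (ne_h + 0.5)) /
                  ((e_bg + 0.5) / (ne_bg + 0.5)))
  N <- length(idx)
  draws <- matrix(sample.int(nrow(ess), N * n_perm, replace = TRUE), n_perm, N)
  e_rand <- rowSums(matrix(is_e[draws], n_perm, N))
  es_rand <- log2(((e_rand) / (N - e_rand)) / (e_bg / ne_bg))
  p <- (sum(es_rand >= es) + 1) / (n_perm + 1)
  tibble::tibble(n_hubs = N, e_hubs = e_h, ne_hubs = ne_h,
                 e_bg = e_bg, ne_bg = ne_bg,
                 es = es, es_haldane = es_hald, p_empirical = p)
}

#' ES across hub sets with BH correction
#'
#' Applies [essentiality_score()] to each named hub set and adjusts the
#' permutation p-values across sets by Benjamini-Hochberg.
#'
#' @param hub_sets Named list of character vectors.
#' @inheritParams essentiality_score
#' @return Tibble, one row per hub set, with `p_adjusted`.
#' @export
essentiality_scores <- function(hub_sets, ess, n_perm = 10000,
                                case_insensitive = TRUE) {
  out <- purrr::imap_dfr(hub_sets, function(h, nm)
    dplyr::mutate(essentiality_score(h, ess, n_perm, case_insensitive),
                  hub_set = nm, .before = 1))
  out$p_adjusted <- stats::p.adjust(out$p_empirical, method = "BH")
  out
}

#' Cumulative top-k hub sets ranked by a centrality
#'
#' Ranks genes by decreasing centrality and returns the cumulative top-k
#' sets (the sweep used for centrality-vs-essentiality curves).
#'
#' @param tab A `centrality_table`.
#' @param metric Centrality column name.
#' @param ks Vector of set sizes (default deciles of the node count).
#' @return Named list of character vectors.
#' @export
hub_sets_by_centrality <- function(tab, metric = "pagerank", ks = NULL) {
  ord <- tab$node[order(tab[[metric]], decreasing = TRUE)]
  if (is.null(ks)) ks <- unique(pmax(1, round(length(ord) * (1:10) / 10)))
  stats::setNames(lapply(ks, function(k) ord[seq_len(k)]),
                  paste0("top", ks))
}

#' Organ-specific centrality and expression multiplicity
#'
#' A gene is centrally specific to an organ when it ranks in the top
#' `top_frac` of a centrality measure exclusively in that organ; its
#' centrality multiplicity is the number of organs where it is top-ranked.
#' Expression multiplicity uses a modified Z per organ — (mean expression
#' in the organ minus the median of the per-organ means) divided by the IQR
#' of the per-organ means (type-7 quantiles) — counting organs with Z > 2.
#' Genes with IQR 0 get Z = 0 and are flagged.
#'
#' @param centrality_tables Named list of `centrality_table`s, one per organ.
#' @param exprs Named list of `expression_matrix` objects (same organs), or
#'   a genes x organs matrix of mean expression.
#' @param metric Centrality column (default `"pagerank"`).
#' @param top_frac Top fraction defining centrality (default 0.2).
#' @return Tibble per gene: `gene`, `central_in` (list of organs),
#'   `centrality_multiplicity`, `exclusive`, `expression_multiplicity`,
#'   `iqr_zero`.
#' @export
organ_specificity <- function(centrality_tables, exprs, metric = "pagerank",
                              top_frac = 0.2) {
  if (length(centrality_tables) < 2) stop("need >= 2 organs")
  organs <- names(centrality_tables)
  top <- purrr::map(centrality_tables, function(tab) {
    k <- ceiling(top_frac * nrow(tab))
    tab$node[order(tab[[metric]], decreasing = TRUE)][seq_len(k)]
  })
  mean_mat <- if (is.matrix(exprs)) exprs else {
    genes <- sort(unique(unlist(purrr::map(exprs, "genes"))))
    m <- vapply(exprs, function(e) {
      v <- stats::setNames(rep(NA_real_, length(genes)), genes)
      v[e$genes] <- Matrix::rowMeans(e$counts)
      v
    }, numeric(length(genes)))
    m
  }
  med <- apply(mean_mat, 1, stats::median, na.rm = TRUE)
  iqr <- apply(mean_mat, 1, stats::IQR, na.rm = TRUE, type = 7)
  z <- (mean_mat - med) / ifelse(iqr == 0, Inf, iqr)   # IQR 0 -> Z 0
  genes <- sort(unique(c(unlist(top), rownames(mean_mat))))
  central_in <- purrr::map(genes, function(g)
    organs[vapply(top, function(t) g %in% t, TRUE)])
  emult <- rowSums(z > 2, na.rm = TRUE)
  tibble::tibble(
    gene = genes,
    central_in = central_in,
    centrality_multiplicity = lengths(central_in),
    exclusive = lengths(central_in) == 1,
    expression_multiplicity = ifelse(genes %in% rownames(mean_mat),
                                     emult[genes], 0),
    iqr_zero = ifelse(genes %in% rownames(mean_mat),
                      iqr[genes] == 0, NA)
  )
}

#' Hypergeometric gene-set enrichment with Bonferroni correction
#'
#' Upper-tail hypergeometric p-value per set for a query gene list against
#' a universe; Bonferroni-adjusted over the tested sets.
#'
#' @param query Character vector of query genes (subset of `universe`).
#' @param sets A `gene_set_collection` or named list of character vectors.
#' @param universe Character vector of all candidate genes.
#' @return Tibble `set`, `overlap`, `set_size`, `p`, `p_bonferroni`,
#'   ordered by p.
#' @export
hypergeom_enrichment <- function(query, sets, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(query %in% universe)) stop("query genes must be inside the universe")
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  n_u <- length(universe); n_q <- length(query)
  out <- purrr::imap_dfr(sets, function(s, nm) {
    s <- intersect(s, universe)
    k <- length(intersect(s, query))
    p <- stats::phyper(k - 1, length(s), n_u - length(s), n_q,
                       lower.tail = FALSE)
    tibble::tibble(set = nm, overlap = k, set_size = length(s), p = p)
  })
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  dplyr::arrange(out, .data$p)
}
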