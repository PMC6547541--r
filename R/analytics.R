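#' Five node centralities
#'
#' Degree, normalized betweenness, normalized closeness, PageRank (damping
#' 0.85) and eigenvector centrality, computed on the unweighted undirected
#' graph (signed correlation weights would break shortest-path metrics; an
#' absolute-weight mode is available). Closeness is normalized within each
#' connected component (`(n_c - 1) / sum of distances`); eigenvector
#' centrality is computed on the largest component with zeros elsewhere;
#' PageRank is computed over the full graph and sums to 1.
#'
#' @param g A pruned `igraph` network.
#' @param use_weights Use `|weight|` as edge weights (default FALSE).
#' @return A `centrality_table` tibble: `node`, `degree`, `betweenness`,
#'   `closeness`, `pagerank`, `eigenvector`.
#' @export
network_centralities <- function(g, use_weights = FALSE) {
  if (igraph::vcount(g) == 0) stop("empty graph")
  w <- if (use_weights) abs(igraph::E(g)$weight) else NA
  n <- igraph::vcount(g)
  btw <- igraph::betweenness(g, weights = w, normalized = TRUE)
  clo <- closeness_by_component(g, weights = w)
  pr <- igraph::page_rank(g, damping = 0.85,
                          weights = if (use_weights) w else NA)$vector
  comp <- igraph::components(g)
  giant_id <- which.max(comp$csize)
  eig <- stats::setNames(numeric(n), igraph::V(g)$name)
  giant <- which(comp$membership == giant_id)
  sub <- igraph::induced_subgraph(g, giant)
  ec <- igraph::eigen_centrality(
    sub, weights = if (use_weights) abs(igraph::E(sub)$weight) else NA)$vector
  eig[igraph::V(sub)$name] <- ec
  tibble::tibble(
    node = igraph::V(g)$name,
    degree = as.numeric(igraph::degree(g)),
    betweenness = as.numeric(btw),
    closeness = as.numeric(clo),
    pagerank = as.numeric(pr),
    eigenvector = as.numeric(eig)
  ) -> out
  class(out) <- c("centrality_table", class(out))
  out
}

# closeness normalized per component: (n_c - 1) / sum_{u in comp} d(v, u)
closeness_by_component <- function(g, weights = NA) {
  comp <- igraph::components(g)
  out <- numeric(igraph::vcount(g))
  for (cid in seq_len(comp$no)) {
    idx <- which(comp$membership == cid)
    if (length(idx) == 1) { out[idx] <- 0; next }
    sub <- igraph::induced_subgraph(g, idx)
    d <- igraph::distances(sub, weights = if (length(weights) == 1 &&
                                              is.na(weights)) NA else
                             abs(igraph::E(sub)$weight))
    out[idx] <- (length(idx) - 1) / rowSums(d)
  }
  out
}

#' Centrality change between two networks
#'
#' For one metric, joins the centralities of the two networks, computes
#' `delta = c_b - c_a`, and returns the `top_n` nodes ranked by `|delta|`.
#' Nodes present in only one network receive centrality 0 in the other and
#' are flagged (`in_both = FALSE`).
#'
#' @param tab_a,tab_b `centrality_table`s for networks A and B.
#' @param metric One of `"degree"`, `"betweenness"`, `"closeness"`,
#'   `"pagerank"`, `"eigenvector"`.
#' @param top_n Number of top-changing nodes to return (default 1000).
#' @param de Optional differential-expression tibble with columns `gene`
#'   and `p` to join onto the result.
#' @return Tibble `node`, `c_a`, `c_b`, `delta`, `in_both` (+ `de_p`),
#'   ordered by decreasing `|delta|`.
#' @export
delta_centrality <- function(tab_a, tab_b, metric = "pagerank", top_n = 1000,
                             de = NULL) {
  stopifnot(metric %in% names(tab_a), metric %in% names(tab_b))
  if (!length(intersect(tab_a$node, tab_b$node)))
    stop("no shared nodes between the two networks")
  a <- tibble::tibble(node = tab_a$node, c_a = tab_a[[metric]])
  b <- tibble::tibble(node = tab_b$node, c_b = tab_b[[metric]])
  out <- dplyr::full_join(a, b, by = "node")
  out$in_both <- !is.na(out$c_a) & !is.na(out$c_b)
  out$c_a[is.na(out$c_a)] <- 0
  out$c_b[is.na(out$c_b)] <- 0
  out$delta <- out$c_b - out$c_a
  if (!is.null(de))
    out <- dplyr::left_join(out, dplyr::rename(de, de_p = "p"),
                            by = c(node = "gene"))
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$delta)))
  utils::head(out, top_n)
}

#' Genes shifting consistently in all five centralities
#'
#' Returns genes whose deltas are non-zero and share the same sign across
#' all five centrality measures between two networks (strict consensus).
#'
#' @param tab_a,tab_b `centrality_table`s for networks A and B.
#' @return Tibble `node`, `direction` (+1 increase / -1 decrease), plus the
#'   five per-metric deltas.
#' @export
consensus_shift <- function(tab_a, tab_b) {
  metrics <- c("degree", "betweenness", "closeness", "pagerank", "eigenvector")
  deltas <- purrr::map(metrics, function(m) {
    d <- delta_centrality(tab_a, tab_b, metric = m, top_n = Inf)
    tibble::tibble(node = d$node, !!paste0("d_", m) := d$delta)
  })
  out <- purrr::reduce(deltas, dplyr::inner_join, by = "node")
  dm <- as.matrix(out[, -1])
  sgn <- sign(dm)
  consistent <- apply(sgn, 1, function(s) all(s == 1) || all(s == -1))
  out <- out[consistent, , drop = FALSE]
  out$direction <- unname(sign(dm[consistent, 1]))
  dplyr::relocate(out, "node", "direction")
}

#' Detect correlation inversions between two conditions
#'
#' Pairs present in either correlation table are looked up in both; records
#' a sign flip when the combined correlations have opposite (non-zero)
#' signs, with `strength = rho_a - rho_b`. Flips with `|strength|` above
#' `strong` (default 1) are flagged as strong inversions.
#'
#' @param corr_a,corr_b `correlation_table`s for the two conditions.
#' @param strong Threshold on `|strength|` for the strong flag (default 1).
#' @param kept_only Restrict to pairs kept in at least one condition
#'   (default TRUE).
#' @return Tibble `gene1`, `gene2`, `rho_a`, `rho_b`, `strength`,
#'   `is_sign_flip`, `is_strong`, sorted by decreasing `|strength|`.
#' @export
find_inversions <- function(corr_a, corr_b, strong = 1.0, kept_only = TRUE) {
  sel <- function(tab) {
    t2 <- tibble::as_tibble(tab)[, c("gene1", "gene2", "rho_combined",
                                     if ("kept" %in% names(tab)) "kept")]
    t2
  }
  a <- sel(corr_a); b <- sel(corr_b)
  out <- dplyr::inner_join(a, b, by = c("gene1", "gene2"),
                           suffix = c("_a", "_b"))
  if (kept_only && all(c("kept_a", "kept_b") %in% names(out)))
    out <- out[out$kept_a | out$kept_b, , drop = FALSE]
  out <- tibble::tibble(
    gene1 = out$gene1, gene2 = out$gene2,
    rho_a = out$rho_combined_a, rho_b = out$rho_combined_b)
  out$strength <- out$rho_a - out$rho_b
  out$is_sign_flip <- sign(out$rho_a) * sign(out$rho_b) < 0
  out$is_strong <- out$is_sign_flip & abs(out$strength) > strong
  dplyr::arrange(out, dplyr::desc(abs(.data$strength)))
}

#' Compare two inferred networks end to end
#'
#' Per-metric centrality deltas, the strict consensus shift, and the
#' correlation-inversion list for two conditions.
#'
#' @param net_a,net_b Pruned `igraph` networks.
#' @param corr_a,corr_b Matching `correlation_table`s (optional; inversions
#'   skipped when absent).
#' @param top_n Top changing nodes per metric (default 1000).
#' @return List with `centrality_a`, `centrality_b`, `delta` (named list of
#'   tibbles per metric), `consensus`, `inversions`.
#' @export
compare_grn <- function(net_a, net_b, corr_a = NULL, corr_b = NULL,
                        top_n = 1000) {
  ca <- network_centralities(net_a)
  cb <- network_centralities(net_b)
  metrics <- c("degree", "betweenness", "closeness", "pagerank", "eigenvector")
  deltas <- stats::setNames(
    purrr::map(metrics, ~delta_centrality(ca, cb, metric = .x, top_n = top_n)),
    metrics)
  inv <- if (!is.null(corr_a) && !is.null(corr_b))
    find_inversions(corr_a, corr_b) else NULL
  list(centrality_a = ca, centrality_b = cb, delta = deltas,
       consensus = consensus_shift(ca, cb), inversions = inv)
}
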