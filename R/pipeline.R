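#' Infer a gene regulatory network from raw counts
#'
#' The end-to-end path: library-size normalization, expressed-gene mask,
#' recursive Ward clustering with per-branch highly variable genes, noise
#' model, pairwise-cluster differential expression into the Z-score matrix,
#' Z-space correlations with the adaptive top-fraction threshold and
#' Spearman control, GO sub-setting against the regulator annotation,
#' pruning, global statistics and the five node centralities.
#'
#' @param counts An `expression_matrix` of raw counts, or a path readable
#'   by [read_counts()].
#' @param regulators Character vector of regulator genes, or a path for
#'   [read_regulators()].
#' @param seed Integer seed governing every stochastic stage (default 1).
#' @param fraction Adaptive-threshold fraction (default 0.001).
#' @param out_dir Optional directory; when given, writes the edge list,
#'   GraphML, cluster assignments, Z-scores, stats JSON, centrality TSV and
#'   a provenance JSON there.
#' @param powerlaw Compute the degree power-law bootstrap p (default FALSE
#'   here; see [network_stats()]).
#' @param ... Passed to [zscore_pipeline()].
#' @return A `grn_result` list: `network` (igraph), `stats`, `centrality`,
#'   `corr`, `clustering`, `z`, `call_config`.
#' @export
infer_grn <- function(counts, regulators, seed = 1, fraction = 0.001,
                      out_dir = NULL, powerlaw = FALSE, ...) {
  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(regulators) && length(regulators) == 1 &&
      file.exists(regulators)) regulators <- read_regulators(regulators)
  set.seed(seed)
  run <- zscore_pipeline(counts, fraction = fraction, ...)
  net <- build_network(run$corr, regulators)
  stats_tab <- network_stats(net, powerlaw = powerlaw)
  cent <- network_centralities(net)
  cfg <- list(seed = seed, fraction = fraction,
              n_genes_in = length(counts$genes),
              n_cells_in = length(counts$cells),
              n_genes_used = length(run$expr$genes),
              n_clusters = length(unique(run$z$clusters)),
              rho_thresh = igraph::graph_attr(net, "rho_thresh"))
  out <- structure(list(network = net, stats = stats_tab, centrality = cent,
                        corr = run$corr, clustering = run$clustering,
                        z = run$z, call_config = cfg),
                   class = "grn_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_edge_list(net, file.path(out_dir, "network_edges.tsv"))
    write_graphml(net, file.path(out_dir, "network.graphml"))
    if (inherits(run$clustering, "cluster_tree"))
      write_clusters(run$clustering, file.path(out_dir, "clusters.tsv"),
                     file.path(out_dir, "cluster_tree.json"))
    write_zscores(run$z, file.path(out_dir, "zscores.tsv"))
    write_network_stats(stats_tab, file.path(out_dir, "network_stats.json"))
    utils::write.table(cent, file.path(out_dir, "centrality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(cfg, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  out
}

#' @export
print.grn_result <- function(x, ...) {
  cat(sprintf("grn_result: %d nodes, %d edges (rho_thresh %.3f, %d clusters)\n",
              igraph::vcount(x$network), igraph::ecount(x$network),
              x$call_config$rho_thresh, x$call_config$n_clusters))
  invisible(x)
}

#' Tidy a fitted network result: the edge table
#' @param x A `grn_result`.
#' @param ... Unused.
#' @return Tibble `gene1`, `gene2`, `weight`.
#' @export
tidy.grn_result <- function(x, ...) {
  el <- igraph::as_data_frame(x$network, what = "edges")
  tibble::tibble(gene1 = el$from, gene2 = el$to, weight = el$weight)
}

#' One-row summary of a fitted network result
#' @param x A `grn_result`.
#' @param ... Unused.
#' @return The `network_stats` row with `rho_thresh` and `n_clusters`.
#' @export
glance.grn_result <- function(x, ...) {
  dplyr::mutate(x$stats, rho_thresh = x$call_config$rho_thresh,
                n_clusters = x$call_config$n_clusters)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
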