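#' Assemble a regulatory network from kept correlations
#'
#' Turns the kept pairs of a `correlation_table` into an undirected signed
#' weighted graph, applies the GO sub-setting (edges where neither endpoint
#' is an annotated regulator of gene expression are discarded) and prunes
#' isolated nodes and small components.
#'
#' @param tab A `correlation_table` with `kept` flags.
#' @param regulators Character vector of regulator gene identifiers
#'   (e.g. genes annotated under "regulation of gene expression").
#' @param min_component_frac Components smaller than this fraction of the
#'   current node count are dropped (default 0.01).
#' @return An `igraph` graph with vertex attribute `regulator`, edge
#'   attribute `weight` (the signed combined correlation), and graph
#'   attributes `rho_thresh` and `pruning_log`.
#' @export
build_network <- function(tab, regulators, min_component_frac = 0.01) {
  kept <- tab[tab$kept, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = kept$gene1, to = kept$gene2,
               weight = kept$rho_combined),
    directed = FALSE)
  g <- igraph::set_graph_attr(g, "rho_thresh",
                              if (nrow(kept)) kept$rho_thresh[1] else NA_real_)
  g <- go_subset(g, regulators)
  prune_network(g, min_component_frac)
}

#' GO sub-setting: keep only putative regulatory edges
#'
#' Removes every edge for which neither endpoint is in the regulator set;
#' remaining edges represent putative (possibly indirect) regulatory links.
#' Marks vertices with a logical `regulator` attribute.
#'
#' @param g An `igraph` graph.
#' @param regulators Non-empty character vector of regulator genes.
#' @return The filtered graph (isolated nodes are NOT yet removed; see
#'   [prune_network()]).
#' @export
go_subset <- function(g, regulators) {
  if (length(regulators) == 0)
    stop("empty regulator set would delete the whole network")
  is_reg <- igraph::V(g)$name %in% regulators
  g <- igraph::set_vertex_attr(g, "regulator", value = is_reg)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  drop <- !(is_reg[ends[, 1]] | is_reg[ends[, 2]])
  igraph::delete_edges(g, igraph::E(g)[drop])
}

#' Prune isolated nodes and small components
#'
#' Iterates two cleaning steps to a fixpoint: drop zero-degree nodes, then
#' drop connected components smaller than `min_frac` of the CURRENT node
#' count. The sequence of removals is recorded in the graph attribute
#' `pruning_log`.
#'
#' @param g An `igraph` graph.
#' @param min_frac Minimum component size as a fraction of current nodes
#'   (default 0.01).
#' @return The pruned graph.
#' @export
prune_network <- function(g, min_frac = 0.01) {
  log <- character(0)
  repeat {
    changed <- FALSE
    iso <- which(igraph::degree(g) == 0)
    if (length(iso)) {
      log <- c(log, sprintf("removed %d isolated node(s)", length(iso)))
      g <- igraph::delete_vertices(g, iso)
      changed <- TRUE
    }
    if (igraph::vcount(g) == 0)
      stop("network vanished; inspect thresholds")
    comp <- igraph::components(g)
    small <- which(comp$csize < min_frac * igraph::vcount(g))
    if (length(small)) {
      drop <- which(comp$membership %in% small)
      log <- c(log, sprintf(
        "removed %d component(s) (%d nodes) below %.3g of network size",
        length(small), length(drop), min_frac))
      g <- igraph::delete_vertices(g, drop)
      changed <- TRUE
    }
    if (igraph::vcount(g) == 0)
      stop("network vanished; inspect thresholds")
    if (!changed) break
  }
  igraph::set_graph_attr(g, "pruning_log",
                         c(igraph::graph_attr(g, "pruning_log"), log))
}

#' Global network statistics
#'
#' The summary block reported per network: node and edge counts, percentage
#' of negative edges, percentage of regulator nodes, density (edges divided
#' by nodes), number of connected components, average shortest path on the
#' largest component (unweighted), modularity of a greedy community
#' partition, and the Kolmogorov-Smirnov goodness-of-fit p-value of a
#' discrete power-law fit to the degree sequence.
#'
#' @param g A pruned `igraph` network.
#' @param powerlaw Compute the bootstrap power-law p-value? (default TRUE;
#'   the bootstrap dominates the run time on large graphs).
#' @param n_boot Semi-parametric bootstrap replicates (default 200).
#' @return A one-row tibble (class `network_stats`).
#' @export
network_stats <- function(g, powerlaw = TRUE, n_boot = 200) {
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  w <- igraph::E(g)$weight
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  asp <- if (igraph::vcount(giant) > 1)
    igraph::mean_distance(giant, weights = NA) else NA_real_
  gu <- igraph::simplify(g)
  mod <- if (m > 0)
    igraph::modularity(igraph::cluster_fast_greedy(gu, weights = NA))
  else NA_real_
  reg <- igraph::V(g)$regulator
  out <- tibble::tibble(
    n_nodes = n,
    n_edges = m,
    pct_negative_edges = if (m > 0 && !is.null(w)) 100 * mean(w < 0) else 0,
    pct_regulators = if (!is.null(reg)) 100 * mean(reg) else NA_real_,
    density = m / n,
    n_components = comp$no,
    avg_shortest_path = asp,
    modularity = mod,
    powerlaw_ks_p = if (powerlaw)
      powerlaw_ks_pvalue(igraph::degree(gu), n_boot = n_boot) else NA_real_
  )
  class(out) <- c("network_stats", class(out))
  out
}

#' Bootstrap goodness-of-fit p for a discrete power-law degree fit
#'
#' Clauset-style test: the discrete power law is fitted by maximum
#' likelihood with the lower cutoff `xmin` chosen by KS minimization
#' (igraph's plfit); the p-value is the fraction of semi-parametric
#' bootstrap replicates (data below `xmin` resampled empirically, data
#' above drawn from the fitted law) whose refitted KS statistic is at least
#' the observed one. `p > 0.01` is the conventional bar for "the power law
#' is a plausible fit" (scale-free topology).
#'
#' @param degrees Degree sequence (non-negative integers).
#' @param n_boot Bootstrap replicates (default 200).
#' @param min_tail Smallest tail size an `xmin` candidate may leave
#'   (default 50): without this floor the KS minimization can retreat into
#'   a tiny tail where any distribution looks power-law and the test has
#'   no power.
#' @param alpha_max Largest admissible exponent (default 6). Scale-free
#'   degree distributions have exponents around 2-3; a "power law" fitted
#'   with an exponent of 15 to a narrow tail window is not scale-free
#'   topology in any meaningful sense, so such candidates are excluded
#'   from the KS minimization. If no admissible fit exists the hypothesis
#'   is rejected outright (floor p).
#' @return Scalar p-value in `[1/(n_boot+1), 1]`.
#' @export
powerlaw_ks_pvalue <- function(degrees, n_boot = 200, min_tail = 50,
                               alpha_max = 6) {
  d <- degrees[degrees > 0]
  if (length(d) < 10) return(NA_real_)
  fit_restricted <- function(x) {
    cand <- sort(unique(x))
    cand <- cand[vapply(cand, function(v) sum(x >= v), 0L) >=
                   min(min_tail, length(x))]
    if (length(cand) == 0) cand <- min(x)
    fits <- lapply(cand, function(v)
      tryCatch(igraph::fit_power_law(x, xmin = v, implementation = "plfit"),
               error = function(e) NULL))
    ok <- which(!vapply(fits, is.null, TRUE))
    ok <- ok[vapply(fits[ok], function(f) f$alpha, 0) <= alpha_max]
    if (length(ok) == 0) return(NULL)
    ks <- vapply(fits[ok], function(f) f$KS.stat, 0)
    f <- fits[ok][[which.min(ks)]]
    f$xmin <- cand[ok][which.min(ks)]
    f
  }
  fit <- fit_restricted(d)
  if (is.null(fit)) return(1 / (n_boot + 1))
  xmin <- fit$xmin; alpha <- fit$alpha; ks_obs <- fit$KS.stat
  n <- length(d)
  ntail <- sum(d >= xmin)
  body <- d[d < xmin]
  # discrete power-law sampler via inverse transform on the truncated tail
  xs <- xmin:(max(d) * 10L)
  pmf <- xs^(-alpha); pmf <- pmf / sum(pmf)
  cdf <- cumsum(pmf)
  exceed <- 0L
  for (b in seq_len(n_boot)) {
    take_tail <- stats::rbinom(1, n, ntail / n)
    syn <- c(if (take_tail > 0) xs[findInterval(stats::runif(take_tail), cdf) + 1L],
             if (n - take_tail > 0 && length(body) > 0)
               sample(body, n - take_tail, replace = TRUE))
    if (length(syn) < 10) next
    f2 <- fit_restricted(syn)
    if (!is.null(f2) && !is.na(f2$KS.stat) && f2$KS.stat >= ks_obs)
      exceed <- exceed + 1L
  }
  (exceed + 1) / (n_boot + 1)
}

#' @export
glance.network_stats <- function(x, ...) x

#' Network statistics as JSON
#' @param x A `network_stats` row.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_network_stats <- function(x, path) {
  jsonlite::write_json(as.list(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
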