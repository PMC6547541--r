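# Shared fixtures, built in code at test time.

# small two-population count matrix with marker genes
two_pop_counts <- function(n_genes = 120, n_per = 40, n_markers = 20,
                           fold = 6, seed = 1) {
  set.seed(seed)
  mu <- rgamma(n_genes, 2, scale = 8)
  lf <- rep(1, n_genes)
  markers <- seq_len(n_markers)
  lf[markers] <- fold
  m1 <- matrix(rpois(n_genes * n_per, mu), n_genes, n_per)
  m2 <- matrix(rpois(n_genes * n_per, mu * lf), n_genes, n_per)
  list(expr = expression_matrix(cbind(m1, m2)),
       labels = rep(1:2, each = n_per), markers = markers)
}

# homogeneous poisson population (null data)
null_counts <- function(n_genes = 300, n_cells = 80, seed = 1) {
  set.seed(seed)
  mu <- exp(rnorm(n_genes, 1, 1.2))
  expression_matrix(matrix(rpois(n_genes * n_cells, mu), n_genes, n_cells))
}

poisson_model <- function(expr, seed = 99) {
  e <- if (expr$normalized) expr else normalize_counts(expr)
  set.seed(seed)
  noise_model_poisson(e)
}

# brute-force centrality oracles (independent of igraph)
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  stopifnot(isSymmetric(unname(adj)))
  # BFS all-pairs distances
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] > 0)
        new <- nb[d[nb] == Inf]
        d[new] <- d[v] + 1
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d
  }
  # closeness normalized within component
  clo <- vapply(seq_len(n), function(v) {
    comp <- which(is.finite(dist[v, ]))
    if (length(comp) <= 1) return(0)
    (length(comp) - 1) / sum(dist[v, comp])
  }, 0)
  # betweenness by explicit shortest-path enumeration (Brandes-free, tiny n)
  npaths <- matrix(0, n, n)
  btw <- rep(0, n)
  # count shortest paths via DP over distance layers
  for (s in seq_len(n)) {
    sigma <- rep(0, n); sigma[s] <- 1
    ord <- order(dist[s, ])
    for (v in ord) {
      if (!is.finite(dist[s, v]) || v == s) next
      pred <- which(adj[v, ] > 0 & dist[s, ] == dist[s, v] - 1)
      sigma[v] <- sum(sigma[pred])
    }
    npaths[s, ] <- sigma
  }
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == v || t == v || s >= t) next
      if (!is.finite(dist[s, t])) next
      if (dist[s, v] + dist[v, t] == dist[s, t])
        tot <- tot + npaths[s, v] * npaths[v, t] / npaths[s, t]
    }
    btw[v] <- tot
  }
  btw <- btw / ((n - 1) * (n - 2) / 2)
  # pagerank by dense power iteration, damping 0.85
  deg <- rowSums(adj > 0)
  pr <- rep(1 / n, n)
  for (i in 1:500) {
    new <- rep((1 - 0.85) / n, n)
    for (v in seq_len(n)) {
      if (deg[v] > 0) {
        nb <- which(adj[v, ] > 0)
        new[nb] <- new[nb] + 0.85 * pr[v] / deg[v]
      } else {
        new <- new + 0.85 * pr[v] / n
      }
    }
    if (max(abs(new - pr)) < 1e-13) { pr <- new; break }
    pr <- new
  }
  # eigenvector on largest component by power iteration, max-normalized
  comp_id <- rep(NA_integer_, n); cid <- 0
  for (s in seq_len(n)) if (is.na(comp_id[s])) {
    cid <- cid + 1
    comp_id[is.finite(dist[s, ])] <- cid
  }
  big <- which(comp_id == which.max(tabulate(comp_id)))
  a <- adj[big, big, drop = FALSE]
  x <- rep(1, length(big))
  for (i in 1:2000) {
    x2 <- as.numeric(a %*% x)
    x2 <- x2 / sqrt(sum(x2^2))
    if (max(abs(x2 - x)) < 1e-14) { x <- x2; break }
    x <- x2
  }
  eig <- rep(0, n); eig[big] <- abs(x) / max(abs(x))
  list(degree = deg, betweenness = btw, closeness = clo,
       pagerank = pr, eigenvector = eig)
}

random_graph_adj <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  adj + t(adj)
}

adj_to_igraph <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::set_vertex_attr(g, "name", value = paste0("n", seq_len(nrow(adj))))
}
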