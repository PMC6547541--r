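#' Degree distribution on log-log axes
#'
#' A scale-free network shows an approximately straight complementary
#' cumulative degree distribution on log-log axes.
#'
#' @param g An `igraph` network.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(g) {
  d <- igraph::degree(igraph::simplify(g))
  tab <- tibble::tibble(degree = sort(unique(d[d > 0])))
  tab$ccdf <- vapply(tab$degree, function(k) mean(d >= k), 0)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$degree, y = .data$ccdf)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "P(degree ≥ k)",
                  title = "Degree distribution") +
    ggplot2::theme_minimal()
}

#' Distribution of combined correlations with the adaptive threshold
#'
#' @param tab A `correlation_table` (after [adaptive_threshold()]).
#' @param bins Histogram bins (default 100).
#' @return A ggplot object.
#' @export
plot_correlation_distribution <- function(tab, bins = 100) {
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$rho_combined)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::labs(x = "combined correlation", y = "pairs",
                  title = "Z-space correlations") +
    ggplot2::theme_minimal()
  if (!is.null(tab$rho_thresh))
    p <- p + ggplot2::geom_vline(xintercept = c(-1, 1) * tab$rho_thresh[1],
                                 linetype = "dashed")
  p
}

#' Centrality change between two networks
#'
#' Scatter of per-node centrality in condition A versus condition B; nodes
#' off the diagonal changed their network role.
#'
#' @param delta A tibble from [delta_centrality()].
#' @param label_top Label the top-n nodes by `|delta|` (default 10).
#' @return A ggplot object.
#' @export
plot_delta_centrality <- function(delta, label_top = 10) {
  top <- utils::head(delta, label_top)
  ggplot2::ggplot(delta, ggplot2::aes(x = .data$c_a, y = .data$c_b)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_text(data = top, ggplot2::aes(label = .data$node),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "centrality, network A", y = "centrality, network B") +
    ggplot2::theme_minimal()
}

#' Recovery AUC versus sparsity
#'
#' @param bench Tibble from [benchmark_dropout_auc()].
#' @return A ggplot object (mean +/- SEM per sparsity level).
#' @export
plot_auc_sparsity <- function(bench) {
  summ <- dplyr::summarise(
    dplyr::group_by(bench, .data$sparsity),
    mean_auc = mean(.data$auc),
    sem = stats::sd(.data$auc) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$sparsity, y = .data$mean_auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_auc - .data$sem,
                                          ymax = .data$mean_auc + .data$sem)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "sparsity (zero fraction)", y = "recovery AUC") +
    ggplot2::theme_minimal()
}

#' @rdname plot_degree_distribution
#' @param object A `grn_result`.
#' @param ... Unused.
#' @export
autoplot.grn_result <- function(object, ...)
  plot_degree_distribution(object$network)

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")
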