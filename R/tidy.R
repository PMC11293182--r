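#' Tidy a clustering result
#' @param x An `aknn_clustering`.
#' @param ... Unused.
#' @return Tibble with one row per cell: `cell`, `cluster` and, when
#'   available, the adaptive neighbor count `k`.
#' @export
tidy.aknn_clustering <- function(x, ...) {
  out <- tibble(cell = names(x$labels), cluster = unname(x$labels))
  if (!is.null(x$k_per_cell)) out$k <- x$k_per_cell
  out
}

#' One-row summary of a clustering result
#' @param x An `aknn_clustering`.
#' @param ... Unused.
#' @return Tibble with cell/community counts and the run parameters.
#' @export
glance.aknn_clustering <- function(x, ...) {
  tibble(n_cells = length(x$labels), n_communities = x$n_communities,
         resolution = x$resolution, delta_used = x$delta_used,
         seed = x$seed,
         mean_k = if (is.null(x$k_per_cell)) NA_real_
                  else mean(x$k_per_cell))
}

#' Tidy a delta-search trace
#' @param x An `aknn_delta_trace`.
#' @param ... Unused.
#' @return The `(delta, n_communities)` tibble with a `chosen` flag.
#' @export
tidy.aknn_delta_trace <- function(x, ...) {
  dplyr::mutate(x$trace, chosen = .data$delta == x$chosen_delta)
}

#' One-row summary of a delta search
#' @param x An `aknn_delta_trace`.
#' @param ... Unused.
#' @return Tibble with the chosen delta, jump position and search
#'   parameters.
#' @export
glance.aknn_delta_trace <- function(x, ...) {
  tibble(chosen_delta = x$chosen_delta, jump_index = x$jump_index,
         n_evaluated = nrow(x$trace), resolution = x$resolution,
         prune = x$prune, seed = x$seed)
}

#' Plot a delta-search trace
#'
#' Community count along the descending delta grid, with the chosen
#' delta (just before the overclustering jump) highlighted.
#'
#' @param object An `aknn_delta_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aknn_delta_trace <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$delta, .data$n_communities)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$chosen), size = 2) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey30",
                                           `TRUE` = "firebrick"),
                                guide = "none") +
    ggplot2::geom_vline(xintercept = object$chosen_delta,
                        linetype = "dashed", color = "firebrick") +
    ggplot2::labs(x = expression(delta ~ "(descending)"),
                  y = "communities detected",
                  title = sprintf("delta search: chosen %g",
                                  object$chosen_delta)) +
    ggplot2::theme_minimal()
}

#' Plot benchmark results
#'
#' Mean rare-cell accuracy (and ARI) against the number of rare cells,
#' one line per method, faceted by resolution — the standard view of the
#' adaptive-vs-fixed contrast.
#'
#' @param object An `aknn_benchmark` tibble (raw or summarized).
#' @param metric `"rare_accuracy"` or `"ari"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aknn_benchmark <- function(object, metric = c("rare_accuracy",
                                                       "ari"), ...) {
  metric <- match.arg(metric)
  df <- summarize_benchmark(object)
  ycol <- paste0("mean_", metric)
  ggplot2::ggplot(df, ggplot2::aes(.data$n_rare, .data[[ycol]],
                                   color = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~resolution, labeller = ggplot2::label_both) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "number of rare cells", y = paste("mean", metric)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of an embedding colored by labels or clusters
#'
#' @param embedding An [sc_embedding].
#' @param color Optional per-cell labels (character/factor) or an
#'   `aknn_clustering` whose labels are used.
#' @param dims Two component indices to plot.
#' @return A ggplot.
#' @export
plot_embedding <- function(embedding, color = NULL, dims = c(1, 2)) {
  stopifnot(is(embedding, "sc_embedding"), length(dims) == 2)
  df <- as_tibble(embedding$coords[, dims, drop = FALSE])
  names(df) <- c("dim1", "dim2")
  if (is(color, "aknn_clustering")) color <- factor(color$labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2))
  if (!is.null(color)) {
    df$group <- factor(color)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                          color = .data$group))
  }
  p + ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::labs(x = colnames(embedding$coords)[dims[1]],
                  y = colnames(embedding$coords)[dims[2]],
                  color = NULL) +
    ggplot2::theme_minimal()
}
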