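#' Plot ranked market shares
#'
#' Bar chart of node shares ordered by share descending. Requires ggplot2.
#'
#' @param volumes As in [market_shares()].
#' @param top Show only the `top` largest nodes (default 15).
#' @return A ggplot object.
#' @export
plot_market_shares <- function(volumes, top = 15) {
  .need_ggplot()
  d <- utils::head(market_shares(volumes), top)
  d$node <- factor(d$node, levels = rev(d$node))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$share, y = .data$node)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "market share", y = NULL)
}

#' Plot supply vs demand degree centrality
#'
#' @param centrality Tibble from [degree_centrality()] or
#'   [centrality_table()].
#' @return A ggplot object.
#' @export
plot_centrality <- function(centrality) {
  .need_ggplot()
  ggplot2::ggplot(centrality,
                  ggplot2::aes(x = .data$relative_out, y = .data$relative_in,
                               label = .data$node)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 2.8) +
    ggplot2::labs(x = "supply centrality (%)", y = "demand centrality (%)")
}

#' Heatmap of an OD matrix
#'
#' @param object An `od_matrix`.
#' @param ... Unused.
#' @return A ggplot object (log-scaled fill on positive flows).
#' @export
autoplot.od_matrix <- function(object, ...) {
  .need_ggplot()
  d <- tidy(object, keep_zeros = FALSE)
  names(d)[3] <- "heads"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$destination, y = .data$source,
                                  fill = log10(.data$heads))) +
    ggplot2::geom_tile() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(fill = "log10 heads")
}

#' Generic autoplot (re-exported pattern for suggests-only ggplot2)
#' @param object Object to plot.
#' @param ... Passed to methods.
#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package", call. = FALSE)
}
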