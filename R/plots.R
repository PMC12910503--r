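# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_histogram geom_boxplot labs scale_fill_viridis_c theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot an AUROC (or correlation) by distance curve
#'
#' @param object A `distance_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot distance_curve
#' @export
autoplot.distance_curve <- function(object, ...) {
  metric <- attr(object, "metric") %||% "value"
  tab <- as_tibble(object)
  ycol <- if (paste0("mean_", metric) %in% names(tab)) paste0("mean_", metric)
  else metric
  ggplot(dplyr::distinct(tab[c("distance", ycol)]),
         aes(x = .data$distance, y = .data[[ycol]])) +
    geom_line() + geom_point() +
    labs(x = "pairwise distance (bases)", y = metric) +
    theme_minimal()
}

#' Heatmap of a chromatin state-pair matrix
#'
#' Rows index the upstream window's state, columns the downstream one;
#' masked (low-coverage) cells are blank.
#'
#' @param object A `state_pair_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot state_pair_matrix
#' @export
autoplot.state_pair_matrix <- function(object, ...) {
  states <- rownames(object)
  tab <- tibble::tibble(
    upstream = factor(rep(states, times = ncol(object)), levels = states),
    downstream = factor(rep(colnames(object), each = nrow(object)),
                        levels = rev(states)),
    value = as.vector(object))
  ggplot(tab, aes(x = .data$upstream, y = .data$downstream,
                  fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(na.value = "grey85") +
    labs(x = "upstream state", y = "downstream state",
         fill = "weighted mean\npercentile",
         title = sprintf("pairwise distance %.0f", attr(object, "d"))) +
    theme_minimal()
}

#' Histogram of a score table
#'
#' Forty bins spanning \[0, 1\], mirroring the usual presentation of the
#' score distribution.
#'
#' @param object An `epair_score_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot epair_score_table
#' @export
autoplot.epair_score_table <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$score)) +
    geom_histogram(breaks = seq(0, 1, by = 0.025), closed = "left") +
    labs(x = sprintf("%s score", attr(object, "kind") %||% ""), y = "pairs") +
    theme_minimal()
}

#' Boxplots of state-pair categories across score kinds
#'
#' @param object A `state_category_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot state_category_summary
#' @export
autoplot.state_category_summary <- function(object, ...) {
  tab <- tidyr::unnest(object$summary, "values")
  ggplot(tab, aes(x = .data$category, y = .data$values, fill = .data$kind)) +
    geom_boxplot() +
    labs(x = NULL, y = "weighted mean percentile", fill = "score") +
    theme_minimal()
}
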