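#' @importFrom ggplot2 ggplot aes geom_col geom_point geom_abline labs
#'   facet_wrap theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a filter cascade as stage counts
#'
#' @param object a `cascade_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cascade_result <- function(object, ...) {
  df <- tidy.cascade_result(object)
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot(df, aes(x = .data$stage, y = .data$count)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "compounds remaining",
         title = object$group %||% "filter cascade") +
    theme_minimal()
}

#' Plot Ki rank against docking-score rank
#'
#' Perfect concordance lies on the diagonal.
#'
#' @param object a `validation_result` with a computed correlation.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.validation_result <- function(object, ...) {
  df <- tidy.validation_result(object)
  assert_that(nrow(df) > 0, "no correlation available to plot")
  ggplot(df, aes(x = .data$ki_rank, y = .data$score_rank)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_point(size = 3, colour = "firebrick") +
    labs(x = "rank of Ki (ascending)", y = "rank of total score (descending)",
         title = sprintf("Spearman rho = %s",
                         format_report_number(object$correlation$rho))) +
    theme_minimal()
}

#' Plot flavor frequencies of a screening group
#'
#' @param object an `association_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.association_result <- function(object, ...) {
  df <- object$flavor_frequencies
  df$flavor <- factor(df$flavor, levels = FLAVORS)
  ggplot(df, aes(x = .data$flavor, y = .data$fraction)) +
    geom_col(fill = "darkorange") +
    labs(x = NULL, y = "fraction of traced medicines",
         title = object$group %||% "flavor frequencies") +
    theme_minimal()
}

#' Plot the target-flavor-function network edge weights
#'
#' A faceted edge-weight chart of the tripartite summary network (for a
#' proper graph layout, convert the edge list with
#' `igraph::graph_from_data_frame()`).
#'
#' @param edges edge tibble from [build_flavor_network()].
#' @return a ggplot.
#' @export
plot_flavor_network <- function(edges) {
  assert_that(nrow(edges) > 0, "empty network")
  ggplot(edges, aes(x = .data$to, y = .data$weight, fill = .data$to_type)) +
    geom_col() +
    facet_wrap(~from, scales = "free_x") +
    labs(x = NULL, y = "edge weight", fill = NULL) +
    theme_minimal()
}
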