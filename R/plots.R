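# ggplot2 views of the pipeline's result tables.

#' Family-membership bar chart for a discovery result
#'
#' @param object A `mir_discovery` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mir_discovery <- function(object, ...) {
  fam <- object$family_summary
  ggplot2::ggplot(fam, ggplot2::aes(
    x = stats::reorder(.data$family, -.data$members),
    y = .data$members
  )) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "miRNA family", y = "members",
                  title = "Predicted miRNA families") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Mature-length histogram of validated candidates
#'
#' @param candidates Candidate tibble (see [predict_precursors()]).
#' @return A ggplot object.
#' @export
plot_mature_lengths <- function(candidates) {
  d <- mutate(candidates, mature_length = .data$mature_end - .data$mature_start)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$mature_length))) +
    ggplot2::geom_bar(fill = "#41ab5d") +
    ggplot2::labs(x = "mature miRNA length (nt)", y = "count",
                  title = "Mature length distribution") +
    ggplot2::theme_minimal()
}

#' Log2 fold-change heatmap of expression responses
#'
#' Color encodes the log2 stress/control change per gene and group x tissue
#' cell (not absolute expression); grey cells were undetected in at least
#' one condition.
#'
#' @param summary Output of [summarize_expression()].
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(summary) {
  d <- expression_directions(summary) |>
    mutate(unit = paste(.data$group, .data$tissue, sep = "\n"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$unit, y = .data$gene,
                                  fill = .data$log2_ratio)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", na.value = "grey85",
                                  name = "log2 stress/control") +
    ggplot2::labs(x = NULL, y = NULL, title = "Expression response") +
    ggplot2::theme_minimal()
}
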