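#' Plot a pattern table
#'
#' Score distribution over all patterns with the top-scoring patterns
#' labelled — the quick visual check that a handful of pathway pairs stand
#' out from the random-pairing background.
#'
#' @param object A `pattern_table` (see [frequency_scores()]).
#' @param top Number of top patterns to highlight (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pattern_table <- function(object, top = 10, ...) {
  tbl <- as_tibble(as.data.frame(object))
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$score))
  tbl$rank <- seq_len(nrow(tbl))
  tbl$highlight <- tbl$rank <= top
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlight), show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00", `FALSE` = "grey60")) +
    ggplot2::labs(x = "pattern rank", y = "frequency score S",
                  title = "Pathway-pair pattern enrichment") +
    ggplot2::theme_minimal()
}

#' Plot a grid-search surface
#'
#' Cross-validation accuracy over the (c, g) grid, log2 axes.
#'
#' @param object A `grid_search` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grid_search <- function(object, ...) {
  grid <- object$grid
  if (length(unique(grid$g)) == 1L) {
    return(
      ggplot2::ggplot(grid, ggplot2::aes(x = log2(.data$c), y = .data$accuracy)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::labs(x = "log2 c", y = "CV accuracy",
                      title = sprintf("Grid search (%s kernel)", object$kind)) +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(grid, ggplot2::aes(x = log2(.data$c), y = log2(.data$g),
                                     fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "log2 c", y = "log2 g", fill = "CV acc",
                  title = sprintf("Grid search (%s kernel)", object$kind)) +
    ggplot2::theme_minimal()
}

#' Plot a repeated-split evaluation table
#'
#' One point per run and metric, with the average row drawn as a horizontal
#' reference per metric.
#'
#' @param object A `split_eval` tibble (see [repeated_split_eval()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.split_eval <- function(object, ...) {
  tbl <- as_tibble(as.data.frame(object))
  long <- tidyr::pivot_longer(tbl, c("acc", "sn", "sp", "f1"),
                              names_to = "metric", values_to = "value")
  runs <- dplyr::filter(long, .data$run != "average")
  avg <- dplyr::filter(long, .data$run == "average")
  ggplot2::ggplot(runs, ggplot2::aes(x = as.integer(.data$run), y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = avg, ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "#0072B2") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "run", y = NULL, title = "Repeated independent splits") +
    ggplot2::theme_minimal()
}
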