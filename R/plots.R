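#' Dot plot of two genomes from their anchor set
#'
#' Draws each anchor as a diagonal segment in (reference, query) coordinate
#' space; a collinear pair shows one broken diagonal, while displaced
#' segments reveal transposed copies.
#'
#' @param anchors Anchor tibble from [find_anchors()] (or the `dotplot`
#'   element of [compare_genomes()]).
#' @return A ggplot object.
#' @export
plot_dotplot <- function(anchors) {
  ggplot2::ggplot(anchors,
                  ggplot2::aes(x = .data$ref_start, y = .data$qry_start,
                               xend = .data$ref_start + .data$length,
                               yend = .data$qry_start + .data$length)) +
    ggplot2::geom_segment(linewidth = 0.8, colour = "steelblue") +
    ggplot2::labs(x = "reference position (bp)", y = "query position (bp)") +
    ggplot2::theme_minimal()
}

#' @method autoplot timecourse_de
#' @export
autoplot.timecourse_de <- function(object, ...) {
  tb <- object$results
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(boundary = 0, bins = 40, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$q_threshold, linetype = 2) +
    ggplot2::labs(x = "permutation p-value", y = "genes",
                  title = sprintf("%d DEGs at q <= %g", object$degs$n,
                                  object$q_threshold)) +
    ggplot2::theme_minimal()
}

#' @method autoplot lap_result
#' @export
autoplot.lap_result <- function(object, ...) {
  tb <- object$genes
  regions <- object$regions
  gg <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$position_bp / 1e6,
                                         y = .data$smoothed_stat)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::facet_wrap(~strand, ncol = 1) +
    ggplot2::labs(x = "chromosomal position (Mb)",
                  y = "smoothed between-class statistic") +
    ggplot2::theme_minimal()
  if (nrow(regions) > 0) {
    gg <- gg + ggplot2::geom_rect(
      data = regions, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_position / 1e6,
                   xmax = .data$end_position / 1e6,
                   ymin = -Inf, ymax = Inf, fill = .data$direction),
      alpha = 0.25) +
      ggplot2::scale_fill_manual(values = c(up = "red", down = "green4"))
  }
  gg
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
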