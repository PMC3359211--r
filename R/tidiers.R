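#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a time-course DE result
#'
#' @param x A `timecourse_de` object from [timecourse_de()].
#' @param ... Unused.
#' @return Tibble with one row per gene: `gene`, `statistic`, `p`, `q`,
#'   `phase` (`"none"` for genes below threshold).
#' @method tidy timecourse_de
#' @export
tidy.timecourse_de <- function(x, ...) {
  x$results
}

#' @rdname tidy.timecourse_de
#' @return `glance()`: one-row tibble with `n_genes`, `n_degs`,
#'   `percent_degs`, `pi0`, `q_threshold`, `spline_df`, `B`.
#' @method glance timecourse_de
#' @export
glance.timecourse_de <- function(x, ...) {
  tibble::tibble(n_genes = x$n_genes, n_degs = x$degs$n,
                 percent_degs = x$degs$percent, pi0 = x$pi0,
                 q_threshold = x$q_threshold, spline_df = x$spline_df,
                 B = x$B)
}

#' Tidy a LAP region-scan result
#'
#' @param x A `lap_result` object from [lap_scan()].
#' @param ... Unused.
#' @return Tibble with one row per gene: position, strand, raw and smoothed
#'   statistic, p, q.
#' @method tidy lap_result
#' @export
tidy.lap_result <- function(x, ...) {
  x$genes
}

#' @rdname tidy.lap_result
#' @return `glance()`: one-row tibble with `n_genes`, `n_regions`,
#'   `n_up`, `n_down`, `knn`, `B`, `q_threshold`, `fc_threshold`.
#' @method glance lap_result
#' @export
glance.lap_result <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$genes), n_regions = nrow(x$regions),
                 n_up = sum(x$regions$direction == "up"),
                 n_down = sum(x$regions$direction == "down"),
                 knn = x$knn, B = x$B, q_threshold = x$q_threshold,
                 fc_threshold = x$fc_threshold)
}
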