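# ggplot2 views of the main result types.

#' Plot per-guide UMI count distributions with their thresholds
#'
#' Histograms of log10 per-cell pooled UMI counts for a few guides, with the
#' assignment threshold marked — the visual check that the two-component
#' mixture separated in-cell from ambient counts.
#'
#' @param object a `guide_assignment`.
#' @param guides guide ids to show (default: the 6 with most cells).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.guide_assignment <- function(object, guides = NULL, ...) {
  counts <- object$assignments
  pooled <- counts %>%
    group_by(.data$cell_barcode, .data$guide_id) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  if (is.null(guides)) {
    guides <- pooled %>% count(.data$guide_id, sort = TRUE) %>%
      utils::head(6) %>% pull(.data$guide_id)
  }
  df <- pooled %>% filter(.data$guide_id %in% guides)
  thr <- object$thresholds %>% filter(.data$guide_id %in% guides)
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$count))) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60") +
    ggplot2::geom_vline(data = thr,
                        ggplot2::aes(xintercept = log10(.data$threshold)),
                        linetype = 2, colour = "firebrick") +
    ggplot2::facet_wrap(~guide_id, scales = "free_y") +
    ggplot2::labs(x = "log10 UMIs per cell (intact + variants pooled)",
                  y = "cells", title = "UMI thresholds per guide")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a mutation spectrum along the cassette
#'
#' @param spectrum tibble from [mutation_spectrum()].
#' @return a ggplot with cassette regions colour-coded.
#' @export
plot_mutation_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = .data$position, y = .data$count,
                               fill = .data$region)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "cassette position (bp)", y = "mutation events",
                  fill = "region",
                  title = "Mutation spectrum along the guide cassette")
}

#' Plot a depth-accuracy sweep
#'
#' @param sweep tibble with columns `median_umis_per_cell` and `concordance`
#'   (one row per downsampling fraction).
#' @return a ggplot.
#' @export
plot_depth_accuracy <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$median_umis_per_cell,
                                      y = .data$concordance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "median guide UMIs per cell",
                  y = "fraction of cells correctly assigned",
                  title = "Assignment accuracy vs sequencing depth")
}
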