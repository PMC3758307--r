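#' Manhattan plot of an association scan
#'
#' @param records Association tibble (e.g. from [best_model()]).
#' @param map Marker map (`marker`, `chrom`, `bp`).
#' @param sig,suggestive Threshold lines drawn at `-log10` of these values
#'   (defaults taken from the scan's thresholds when present).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(records, map, sig = NULL, suggestive = NULL) {
  dat <- manhattan_data(records, map)
  thr <- attr(dat, "thresholds")
  sig <- sig %||% unname(thr["sig"])
  suggestive <- suggestive %||% unname(thr["suggestive"])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cum_bp, y = .data$neg_log10_p,
                                    colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(sig), colour = "red",
                        linetype = "solid") +
    ggplot2::geom_hline(yintercept = -log10(suggestive), colour = "blue",
                        linetype = "dashed") +
    ggplot2::labs(x = "Cumulative position (bp)",
                  y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
}

#' Quantile-quantile plot of association p-values
#'
#' @param p Numeric p-values.
#' @return A ggplot object with the y = x reference line and the genomic
#'   inflation factor in the subtitle.
#' @export
plot_qq <- function(p) {
  dat <- qq_data(p)
  ggplot2::ggplot(dat, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](italic(p))),
                  y = expression(Observed ~ -log[10](italic(p))),
                  subtitle = sprintf("lambda = %.3f", genomic_lambda(p))) +
    ggplot2::theme_minimal()
}

#' Depth-panel heat track
#'
#' Fold depth (count over the animal's own mean) by window position and
#' animal, the view in which a divergent non-mapping haplotype shows as a
#' near-zero band in carrier animals.
#'
#' @param depth Long depth tibble.
#' @param grid Window grid.
#' @param calls Optional region-call tibble; called regions are outlined.
#' @return A ggplot object.
#' @export
plot_depth_panel <- function(depth, grid, calls = NULL) {
  fold <- depth_summary(depth, grid)$fold
  p <- ggplot2::ggplot(fold, ggplot2::aes(x = .data$window_start,
                                          y = .data$animal_id,
                                          fill = pmin(.data$fold, 3))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "fold depth", na.value = "grey80") +
    ggplot2::labs(x = "Position (bp)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls)) {
    p <- p + ggplot2::annotate("rect", xmin = calls$start, xmax = calls$end,
                               ymin = -Inf, ymax = Inf, fill = NA,
                               colour = "red", linewidth = 0.4)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for association scans
#'
#' Draws the Manhattan plot when a `map` is supplied, otherwise the QQ plot
#' of the best-model p-values.
#'
#' @param object An `assoc_scan` tibble.
#' @param map Optional marker map.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assoc_scan <- function(object, map = NULL, ...) {
  best <- best_model(object)
  if (is.null(map)) plot_qq(best$p_nominal) else plot_manhattan(best, map)
}
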