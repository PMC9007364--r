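
#' @export
autoplot.sag_sigmoid_fit <- function(object, ...) {
  d <- tibble(time_min = object$times, fluorescence = object$fluorescence)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min, y = .data$fluorescence)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "time (min)", y = "fluorescence")
  if (object$converged) {
    grid <- tibble(time_min = seq(min(d$time_min), max(d$time_min), length.out = 200))
    grid$fit <- object$f0 + object$amplitude /
      (1 + exp(-object$rate * (grid$time_min - object$tinf)))
    p <- p +
      ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit), color = "firebrick") +
      ggplot2::geom_vline(xintercept = object$tinf, linetype = "dashed")
  }
  p
}

#' Histograms of the assembly QC metric panel
#'
#' @param qc A [qc_metrics()] or [qc_table()] tibble.
#' @param bins Histogram bin count.
#' @return A faceted ggplot.
#' @export
plot_qc_histograms <- function(qc, bins = 30L) {
  metrics <- intersect(c("n_contigs", "total_length", "longest_contig",
                         "gc_fraction"), names(qc))
  long <- tidyr::pivot_longer(qc[, c("assembly_id", metrics)],
                              dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", color = "white") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "assemblies")
}

#' Per-clade phylogenetic gain barplot
#'
#' @param gain A [gain_table()] tibble.
#' @param top Number of highest-gain clades to show.
#' @return A ggplot.
#' @export
plot_gain <- function(gain, top = 20L) {
  d <- gain |>
    filter(.data$n_placed_below > 0) |>
    arrange(dplyr::desc(.data$gain_percent)) |>
    head(top) |>
    mutate(node = factor(.data$node_id, levels = rev(.data$node_id)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gain_percent, y = .data$node)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "phylogenetic gain (%)", y = "base-tree node")
}
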