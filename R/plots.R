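#' Windowed statistic along the chromosome
#'
#' Line plot of a windowed statistic (F_ST, Tajima's D) with the locus
#' interval shaded.
#'
#' @param stat_windows tibble from [fst_windows()] or [tajima_windows()]
#' @param locus optional `list(start=, end=)` interval to shade
#' @param ylab y-axis label
#' @return a ggplot
#' @export
plot_window_stat <- function(stat_windows, locus = NULL,
                             ylab = "statistic") {
  p <- ggplot2::ggplot(stat_windows,
                       ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::labs(x = "position (bp)", y = ylab) +
    ggplot2::theme_minimal()
  if (!is.null(locus))
    p <- p + ggplot2::annotate("rect", xmin = locus$start,
                               xmax = locus$end, ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "grey40")
  p
}

#' Genome-wide distribution of a windowed statistic
#'
#' Histogram of the genome-wide values with an arrow marking the focal
#' (locus) maximum — the visual form of a percentile-enrichment claim.
#'
#' @param stat_windows window-statistic tibble
#' @param focal_max the focal maximum to mark (e.g. from
#'   [percentile_rank()])
#' @param xlab x-axis label
#' @return a ggplot
#' @export
plot_stat_distribution <- function(stat_windows, focal_max = NULL,
                                   xlab = "statistic") {
  p <- ggplot2::ggplot(stat_windows, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 60, na.rm = TRUE) +
    ggplot2::labs(x = xlab, y = "windows") +
    ggplot2::theme_minimal()
  if (!is.null(focal_max))
    p <- p + ggplot2::geom_vline(xintercept = focal_max, colour = "red",
                                 linetype = 2)
  p
}

#' LD heat map in the Haploview colour scheme
#'
#' @param ld tibble from [ld_matrix()]
#' @return a ggplot
#' @export
plot_ld_heatmap <- function(ld) {
  ggplot2::ggplot(ld, ggplot2::aes(x = .data$pos_i, y = .data$pos_j,
                                   fill = .data$color_class)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(white = "white", blue = "#4a6fe3",
                                          pink_red = "#d33f49")) +
    ggplot2::labs(x = "position (bp)", y = "position (bp)", fill = "LD") +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
autoplot.pca_result <- function(object, samples = NULL, colour = "morph",
                                ...) {
  df <- tidy(object)
  if (!is.null(samples)) df <- left_join(df, samples, by = "individual")
  aes <- if (!is.null(samples))
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data[[colour]],
                 shape = .data$species)
  else ggplot2::aes(.data$PC1, .data$PC2)
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])) +
    ggplot2::theme_minimal()
}

#' Allele-class frequency trajectories from a simulation
#'
#' @param result a `sim_result`
#' @return a ggplot, one panel per species
#' @export
plot_allele_trajectories <- function(result) {
  lg <- result$generation_log
  ggplot2::ggplot(lg, ggplot2::aes(.data$generation, .data$freq,
                                   colour = factor(.data$class))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = "generation", y = "class frequency",
                  colour = "allele class") +
    ggplot2::theme_minimal()
}
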