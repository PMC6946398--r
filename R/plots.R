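#' Plot the lineage-diversity time course
#'
#' Mean number of uniquely labelled lineages per ovariole against days
#' post heat shock, with one-SD ribbons; the hallmark of transient-clone
#' clearance is a decline over the first one to two weeks.
#'
#' @param object An `fsc_cohort` tibble ([simulate_cohort()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fsc_cohort
#' @export
autoplot.fsc_cohort <- function(object, ...) {
  tc <- diversity_timecourse(object)
  ggplot2::ggplot(tc, ggplot2::aes(x = .data$dphs, y = .data$mean_lineages)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(0, .data$mean_lineages - .data$sd_lineages),
      ymax = .data$mean_lineages + .data$sd_lineages), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "days post heat shock",
                  y = "uniquely labelled lineages per ovariole") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot clone-size fractions by condition
#'
#' Jittered per-ovariole labelled fractions with group means, the display
#' used to compare clone sizes across heat-shock regimens and marking
#' systems.
#'
#' @param data A data frame with columns `condition` and `fraction` (see
#'   [mosaic_fractions()], [compare_clone_sizes()]).
#' @return A ggplot object.
#' @export
plot_clone_sizes <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$condition,
                                     y = .data$fraction)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "red") +
    ggplot2::scale_y_continuous(labels = function(x) 100 * x,
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "labelled cells (%)") +
    ggplot2::theme_minimal()
}

#' Intensity scatterplot of segmented nuclei
#'
#' Per-nucleus mean label-channel intensity against anterior-posterior
#' position, with the fitted label threshold — the plot used to separate
#' marker-negative from marker-positive cells.
#'
#' @param surfaces A `nucleus_surfaces` tibble ([segment_nuclei()]).
#' @param threshold Optional intensity threshold to draw (e.g.
#'   `fit_label_threshold(surfaces$mean_label)$threshold`).
#' @return A ggplot object.
#' @export
plot_intensity_scatter <- function(surfaces, threshold = NULL) {
  p <- ggplot2::ggplot(surfaces, ggplot2::aes(x = .data$x_um,
                                              y = .data$mean_label)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "anterior-posterior position (um)",
                  y = "mean label intensity") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "red")
  }
  p
}
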