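# ggplot2 views of the main result types: a site map along the UTR,
# relative reporter activities, and carrier frequencies with exact CIs.

#' Plot predicted target sites along a UTR
#'
#' One horizontal lane per miRNA; footprints are drawn as thin segments,
#' seed intervals as thick ones, colored by site class. Variants can be
#' overlaid as vertical dashed lines.
#'
#' @param sites A [scan_sites()] result.
#' @param variants Optional polymorphism tibble (needs `position`, `end`,
#'   `snp_id`).
#' @param utr_length Optional UTR length used to fix the x axis.
#' @return A ggplot object.
#' @export
plot_sites <- function(sites, variants = NULL, utr_length = NULL) {
  p <- ggplot2::ggplot(sites) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$footprint_start, xend = .data$footprint_end,
                   y = .data$mirna_name, yend = .data$mirna_name),
      linewidth = 0.6, colour = "grey70") +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$seed_start, xend = .data$seed_end,
                   y = .data$mirna_name, yend = .data$mirna_name,
                   colour = .data$site_type),
      linewidth = 3) +
    ggplot2::labs(x = "3'UTR position (nt)", y = NULL, colour = "site class") +
    ggplot2::theme_minimal()
  if (!is.null(variants) && nrow(variants) > 0L) {
    p <- p + ggplot2::geom_vline(
      data = variants,
      ggplot2::aes(xintercept = (.data$position + .data$end) / 2),
      linetype = "dashed", colour = "red3")
  }
  if (!is.null(utr_length)) {
    p <- p + ggplot2::xlim(1, utr_length)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.polymirts_sites <- function(object, ...) plot_sites(object, ...)

#' Plot relative reporter activity
#'
#' Per-well relative values as jittered points with group means, one panel
#' per construct when present. The horizontal line at 1 marks the
#' scrambled-control level.
#'
#' @param data A `polymirts_relative` tibble (from [relative_luciferase()],
#'   [relative_densitometry()] or [relative_elisa()]).
#' @return A ggplot object.
#' @export
plot_relative_activity <- function(data) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$mirna, y = .data$relative)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "grey80",
                          width = 0.6) +
    ggplot2::geom_jitter(width = 0.1, size = 1.4, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "relative activity (control = 1)") +
    ggplot2::theme_minimal()
  if ("construct" %in% names(data)) {
    p <- p + ggplot2::facet_wrap(~construct)
  }
  if ("analyte" %in% names(data)) {
    p <- p + ggplot2::facet_wrap(~analyte)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.polymirts_relative <- function(object, ...) plot_relative_activity(object)

#' Plot carrier frequencies with exact confidence intervals
#'
#' @param data A `polymirts_carriers` tibble from [carrier_frequency()].
#' @return A ggplot object.
#' @export
plot_carrier_frequency <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$group, y = .data$frequency)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::labs(x = NULL, y = "carrier frequency") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.polymirts_carriers <- function(object, ...) plot_carrier_frequency(object)
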