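# Plot methods for the summary objects.

#' @exportS3Method ggplot2::autoplot
autoplot.ppm_summary <- function(object, ...) {
  d <- as_tibble(object)
  d$component <- factor(d$component, levels = PPM_COMPONENTS)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$component,
                                       y = .data$mean_ppm_eur)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = NULL, y = "cost per patient-month (EUR)") +
    ggplot2::theme_minimal()
  if (!all(is.na(d$ci95_low_eur))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci95_low_eur, ymax = .data$ci95_high_eur),
      width = 0.2)
  }
  if (length(unique(d$stratum)) > 1) {
    p <- p + ggplot2::facet_wrap(~stratum)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.ppm_sensitivity <- function(object, ...) {
  d <- as_tibble(object)
  d$component <- factor(d$component, levels = PPM_COMPONENTS)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component,
                                  y = .data$mean_ppm_eur,
                                  fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "cost per patient-month (EUR)",
                  fill = "scenario") +
    ggplot2::theme_minimal()
}

#' Plot cost ppm by subgroup
#'
#' Point-range plot of one component's ppm across the strata of a
#' stratified summary.
#'
#' @param summary A `ppm_summary` from [stratified_summary()].
#' @param component Component to display (default `"total"`).
#' @return A ggplot object.
#' @export
plot_subgroup_ppm <- function(summary, component = "total") {
  d <- as_tibble(summary)
  d <- d[d$component == component, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_ppm_eur,
                                  y = .data$stratum)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci95_low_eur,
                                          xmax = .data$ci95_high_eur)) +
    ggplot2::labs(x = sprintf("%s cost per patient-month (EUR)", component),
                  y = NULL) +
    ggplot2::theme_minimal()
}
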