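# ggplot2 graphics: concentration-time profiles, VPC bands, ratio forest
# plot, and AUC box-whisker comparisons.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated concentration-time profile
#'
#' @param object A `pbpk_profile` tibble.
#' @param log_y Log-scale the concentration axis.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pbpk_profile <- function(object, log_y = FALSE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h,
                                            y = .data$conc_ug_ml)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "Time (h)", y = "Venous plasma concentration (µg/mL)")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Visual predictive check
#'
#' Overlays the ensemble mean, the 5th-95th centile band and the min-max
#' envelope, optionally with observed points.
#'
#' @param bands A [vpc_bands()] tibble.
#' @param observed Optional tibble `time_h`, `conc_ug_ml` of observations.
#' @param log_y Log-scale the concentration axis.
#' @return A ggplot.
#' @export
plot_vpc <- function(bands, observed = NULL, log_y = FALSE) {
  p <- ggplot2::ggplot(bands, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         fill = "grey65") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), color = "black") +
    ggplot2::labs(x = "Time (h)", y = "Concentration (µg/mL)")
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_point(data = observed,
                                 ggplot2::aes(y = .data$conc_ug_ml),
                                 color = "red")
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Mean predicted/observed ratios with intervals
#'
#' Forest-style display of an evaluation report, with the identity and the
#' 0.5-2 fold-error band marked.
#'
#' @param object A `pk_evaluation` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pk_evaluation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_R, y = .data$cohort)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::geom_vline(xintercept = c(0.5, 2), linetype = 3,
                        color = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$R_lo, xmax = .data$R_hi),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Mean predicted/observed ratio", y = NULL)
}

#' AUC box-whisker comparison across populations
#'
#' @param auc_by_group A tibble with columns `group` and `auc`.
#' @return A ggplot with 5th-95th centile whiskers.
#' @export
plot_auc_boxes <- function(auc_by_group) {
  ggplot2::ggplot(auc_by_group, ggplot2::aes(x = .data$group, y = .data$auc)) +
    ggplot2::stat_summary(
      fun.data = function(y) {
        q <- quantile(y, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
        data.frame(ymin = q[1], lower = q[2], middle = q[3], upper = q[4],
                   ymax = q[5])
      },
      geom = "boxplot", width = 0.5, fill = "grey80"
    ) +
    ggplot2::labs(x = NULL, y = "AUC (µg·h/mL)")
}
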