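#' Plot a power spectrum
#'
#' Channel-mean power density on a log scale with the TF/IAF search windows
#' shaded; individual channels drawn faintly behind.
#'
#' @param object An `eeg_psd`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot eeg_psd
#' @export
autoplot.eeg_psd <- function(object, ...) {
  long <- tidy(object)
  chans <- dplyr::filter(long, .data$channel != "global")
  glob <- dplyr::filter(long, .data$channel == "global")
  ggplot2::ggplot(chans, ggplot2::aes(.data$frequency, .data$psd,
                                      group = .data$channel)) +
    ggplot2::annotate("rect", xmin = 3, xmax = 8, ymin = -Inf, ymax = Inf,
                      alpha = 0.08, fill = "steelblue") +
    ggplot2::annotate("rect", xmin = 6, xmax = 14, ymin = -Inf, ymax = Inf,
                      alpha = 0.08, fill = "firebrick") +
    ggplot2::geom_line(alpha = 0.2, linewidth = 0.3) +
    ggplot2::geom_line(data = glob, color = "black", linewidth = 0.9) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = expression(PSD~(mu*V^2/Hz)),
                  title = object$subject_id) +
    ggplot2::theme_minimal()
}

#' Plot band-wise education contrasts
#'
#' Group mean activity (+/- SE) per frequency band, the figure style used to
#' display an Education x Band interaction; significant Duncan contrasts
#' (band-wise Bonferroni) are marked.
#'
#' @param object A `posthoc_result` from [duncan_posthoc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot posthoc_result
#' @export
autoplot.posthoc_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as.data.frame(object)[, c("band", "mean_low", "mean_high",
                              "significant")],
    cols = c("mean_low", "mean_high"),
    names_to = "edu", values_to = "mean")
  df$edu <- ifelse(df$edu == "mean_low", "Edu-", "Edu+")
  ggplot2::ggplot(df, ggplot2::aes(.data$band, .data$mean,
                                   group = .data$edu,
                                   color = .data$edu)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_point(data = df[df$significant, ],
                        shape = 0, size = 5, color = "black") +
    ggplot2::labs(x = "Band", y = "log10 normalized source activity",
                  color = "Education") +
    ggplot2::theme_minimal()
}

#' Plot simple slopes of an interaction regression
#'
#' Fitted regression lines of the target on the activity predictor within
#' each education level, with the observed points.
#'
#' @param object A `regression_result`.
#' @param data The data the model was fitted on.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot regression_result
#' @export
autoplot.regression_result <- function(object, data = NULL, ...) {
  d <- if (is.null(data)) object$model$model else as.data.frame(data)
  act <- object$design$activity
  tgt <- object$design$target
  edu <- object$design$education
  ggplot2::ggplot(d, ggplot2::aes(.data[[act]], .data[[tgt]],
                                  color = .data[[edu]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.8) +
    ggplot2::labs(x = act, y = tgt, color = edu) +
    ggplot2::theme_minimal()
}

#' Regional activity profile plot
#'
#' Mean (+/- SE) log10 normalized activity per band, faceted by region and
#' colored by education subgroup — the standard display of the regional
#' analysis for one diagnostic group.
#'
#' @param table Long cohort tibble (one diagnostic group).
#' @return A ggplot object.
#' @export
plot_activity_profile <- function(table) {
  agg <- dplyr::summarise(
    dplyr::group_by(table, .data$roi, .data$band, .data$edu),
    mean = mean(.data$activity),
    se = sd(.data$activity) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(.data$band, .data$mean,
                                    group = .data$edu,
                                    color = .data$edu)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se),
                             size = 0.2) +
    ggplot2::facet_wrap(~roi) +
    ggplot2::labs(x = "Band", y = "log10 normalized source activity",
                  color = "Education") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
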