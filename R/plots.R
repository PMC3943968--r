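# ggplot2 views of the main result types.

#' Plot the contamination dose-response of a spike-in experiment
#'
#' Scatter of the directional fold change against the equal-volume plasma/CSF
#' ratio (log10 x), coloured by category when present, with the affected and
#' unaffected thresholds drawn. Visualises the core relation: the higher a
#' protein's plasma/CSF ratio, the stronger the blood-contamination effect.
#'
#' @param df Tibble with `r_volume` and a fold-change column, optionally
#'   `category`.
#' @param fc_col Fold-change column name (default `"fc_high"`).
#' @param fc_affected,fc_unaffected Threshold lines (defaults 1.5, 1.2).
#' @return A ggplot object.
#' @export
plot_spike_response <- function(df, fc_col = "fc_high",
                                fc_affected = 1.5, fc_unaffected = 1.2) {
  assert_cols(df, c("r_volume", fc_col), "spike result")
  p <- ggplot2::ggplot(
    df, ggplot2::aes(x = .data$r_volume, y = .data[[fc_col]])
  ) +
    ggplot2::geom_hline(yintercept = c(fc_unaffected, fc_affected),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "equal-volume plasma/CSF ratio",
      y = "fold change vs clean CSF"
    ) +
    ggplot2::theme_minimal()
  if ("category" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$category), alpha = 0.6)
  } else {
    p + ggplot2::geom_point(alpha = 0.6)
  }
}

#' @describeIn fit_gradient Scatter of per-protein R-squared against the
#'   symmetric end-to-end fold change with the classification thresholds
#'   drawn.
#' @param object A `csf_gradient_fits` tibble.
#' @param ... Unused.
#' @method autoplot csf_gradient_fits
#' @export
autoplot.csf_gradient_fits <- function(object, ...) {
  ggplot2::ggplot(
    filter(object, .data$evaluable),
    ggplot2::aes(x = .data$fc_1_7, y = .data$r_squared)
  ) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = c(1.2, 1.5), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = c(0.3, 0.7), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "fold change, point 1 vs point 7 (symmetric)",
      y = expression(R^2 ~ "of linear fit vs collection point")
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn estimate_blood_fraction Histogram of the per-protein
#'   contamination-fraction estimates with the median marked.
#' @param object A `contamination_estimate`.
#' @method autoplot contamination_estimate
#' @export
autoplot.contamination_estimate <- function(object, ...) {
  ggplot2::ggplot(object$per_protein, ggplot2::aes(x = .data$f_i)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$f_hat, colour = "firebrick") +
    ggplot2::labs(
      x = "per-protein blood fraction estimate",
      y = "proteins",
      title = sprintf("f_hat = %.3f%% blood by volume", 100 * object$f_hat)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the collected-volume effect curve
#'
#' Predicted percent concentration difference for plasma-derived proteins as
#' a function of the collected CSF volume, under a linear rostro-caudal
#' gradient.
#'
#' @param end_to_end_fc,total_volume Gradient model parameters (defaults 1.6,
#'   45 mL).
#' @param relative_to Basis of the percentage (see
#'   [predict_volume_effect()]).
#' @return A ggplot object.
#' @export
plot_volume_effect <- function(end_to_end_fc = 1.6, total_volume = 45,
                               relative_to = "ventricular") {
  v <- seq(0.5, total_volume, length.out = 200)
  df <- tibble(
    collected_volume = v,
    percent_difference = predict_volume_effect(
      v, end_to_end_fc = end_to_end_fc, total_volume = total_volume,
      relative_to = relative_to
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$collected_volume,
                                   y = .data$percent_difference)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "collected CSF volume (mL, from the lumbar end)",
      y = "plasma-protein concentration difference vs full pool (%)"
    ) +
    ggplot2::theme_minimal()
}
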