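# ggplot2 displays for the result objects.

#' Plot a decile calibration table
#'
#' Pre-calibration predictive ratio by predicted-risk decile, with the
#' unity line that calibration enforces.
#'
#' @param object A `franklin_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot franklin_calibration
#' @export
autoplot.franklin_calibration <- function(object, ...) {
  df <- tidy.franklin_calibration(object)
  df$predictive_ratio <- df$mean_predicted / df$mean_observed
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$decile),
                                   y = .data$predictive_ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Predicted-risk decile",
                  y = "Predictive ratio (pre-calibration)",
                  title = "Decile predictive ratios before calibration") +
    ggplot2::theme_minimal()
}

#' Plot within-decile observed-cost dispersion
#'
#' IQR and decile range (90th minus 10th percentile) of observed cost by
#' predicted-risk decile.
#'
#' @param deciles Tibble from [decile_dispersion()].
#' @return A ggplot.
#' @export
plot_decile_dispersion <- function(deciles) {
  long <- tidyr::pivot_longer(deciles[, c("decile", "iqr", "decile_range")],
                              c("iqr", "decile_range"),
                              names_to = "measure", values_to = "usd")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$decile), y = .data$usd,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Predicted-risk decile", y = "Observed cost spread (USD)",
                  fill = NULL,
                  title = "Within-decile observed-cost dispersion") +
    ggplot2::theme_minimal()
}

#' Plot an overpayment curve
#'
#' Mean overpayment per member per year against selection strength, one
#' line per payment model, with the percentile interval band.
#'
#' @param object A `franklin_overpayment_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot franklin_overpayment_curve
#' @export
autoplot.franklin_overpayment_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tau,
                                       y = .data$overpayment_pmpy,
                                       colour = .data$model,
                                       fill = .data$model)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(tau ~ "(selection strength)"),
                  y = "Overpayment, USD per member per year",
                  title = "Favorable-selection overpayment") +
    ggplot2::theme_minimal()
}

#' Plot predicted vs observed cost distributions
#'
#' Overlaid densities of log(cost + offset) for predictions and
#' observations — the distributional alignment the KS statistic
#' summarizes.
#'
#' @param predicted,observed Paired cost-scale vectors.
#' @param offset Log offset `c` (USD).
#' @return A ggplot.
#' @export
plot_cost_distributions <- function(predicted, observed, offset = 1) {
  df <- dplyr::bind_rows(
    tibble(which = "predicted", log_cost = log(predicted + offset)),
    tibble(which = "observed", log_cost = log(observed + offset))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_cost, colour = .data$which)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = sprintf("log(cost + %g)", offset), y = "Density",
                  colour = NULL,
                  title = "Predicted vs observed cost distributions") +
    ggplot2::theme_minimal()
}
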