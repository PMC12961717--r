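# broom-style tidiers for the fitted objects.

#' Tidy a fitted risk model
#'
#' One row per feature with its gain-based importance in the boosted
#' ensemble.
#'
#' @param x A `franklin_risk_model`.
#' @param ... Unused.
#' @return Tibble with `feature`, `gain`, `cover`, `frequency`.
#' @method tidy franklin_risk_model
#' @export
tidy.franklin_risk_model <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  tibble(
    feature = imp$Feature,
    gain = imp$Gain,
    cover = imp$Cover,
    frequency = imp$Frequency
  )
}

#' Glance at a fitted risk model
#'
#' @param x A `franklin_risk_model`.
#' @param ... Unused.
#' @return One-row tibble with `n_features`, `best_iteration`, `max_depth`,
#'   `eta`, `subsample`, `offset`, `calibrated`.
#' @method glance franklin_risk_model
#' @export
glance.franklin_risk_model <- function(x, ...) {
  tibble(
    n_features = length(x$feature_names),
    best_iteration = x$best_iteration,
    max_depth = x$params$max_depth,
    eta = x$params$eta,
    subsample = x$params$subsample,
    offset = x$offset,
    calibrated = !is.null(x$calibration)
  )
}

#' Tidy a decile calibration table
#'
#' @param x A `franklin_calibration`.
#' @param ... Unused.
#' @return The calibration tibble (decile, upper, factor, n,
#'   mean_predicted, mean_observed).
#' @method tidy franklin_calibration
#' @export
tidy.franklin_calibration <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Tidy a cluster model
#'
#' @param x A `franklin_clusters`.
#' @param ... Unused.
#' @return Tibble with `code`, `cluster`.
#' @method tidy franklin_clusters
#' @export
tidy.franklin_clusters <- function(x, ...) {
  tibble(code = names(x$assignment), cluster = unname(x$assignment))
}

#' Glance at a cluster model
#'
#' @param x A `franklin_clusters`.
#' @param ... Unused.
#' @return One-row tibble with `k`, `inertia`, `n_codes`, `seed`.
#' @method glance franklin_clusters
#' @export
glance.franklin_clusters <- function(x, ...) {
  tibble(k = x$k, inertia = x$inertia,
         n_codes = length(x$assignment), seed = x$seed)
}

#' Tidy an evaluation report
#'
#' Stacks the report's tables into one long tibble.
#'
#' @param x A `franklin_evaluation`.
#' @param ... Unused.
#' @return Tibble with `section`, `name`, `value` plus section-specific id
#'   columns where applicable.
#' @method tidy franklin_evaluation
#' @export
tidy.franklin_evaluation <- function(x, ...) {
  fit_long <- tidyr::pivot_longer(x$fit, dplyr::everything(),
                                  names_to = "name", values_to = "value")
  dplyr::bind_rows(
    dplyr::mutate(fit_long, section = "fit", .before = 1),
    dplyr::mutate(
      tidyr::pivot_longer(x$classification, c("sensitivity", "specificity", "precision"),
                          names_to = "name", values_to = "value"),
      section = "classification", .before = 1
    ),
    dplyr::mutate(
      tidyr::pivot_longer(x$error_frequencies, c("overprediction", "underprediction"),
                          names_to = "name", values_to = "value"),
      section = "error_frequencies", .before = 1
    )
  )
}

#' Glance at an evaluation report
#'
#' @param x A `franklin_evaluation`.
#' @param ... Unused.
#' @return The one-row fit metric tibble with the dispersion factors
#'   appended.
#' @method glance franklin_evaluation
#' @export
glance.franklin_evaluation <- function(x, ...) {
  dplyr::bind_cols(x$fit,
                   x$dispersion[, c("sigma", "structural_factor", "residual_factor")])
}
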