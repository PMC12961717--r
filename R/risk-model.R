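# Gradient-boosted log-cost regression on (age, sex, cluster features),
# cost-scale retransformation, and decile predictive-ratio calibration.

#' Build the design matrix and log-cost target for the risk model
#'
#' One row per beneficiary: age, a male indicator, and the k cluster
#' features. The target is `log(observed_cost + offset)`.
#'
#' @param cohort Beneficiary tibble with `id`, `age`, `sex`,
#'   `observed_cost`.
#' @param features Cluster-feature tibble from
#'   [compute_cluster_features()] (column `id` plus feature columns), in
#'   any row order; joined by id.
#' @param offset Log offset `c` in USD (default 1) so zero-cost
#'   beneficiaries have a finite target.
#' @return A list of class `franklin_design` with `x` (numeric matrix),
#'   `y` (log-cost target), `ids`, `observed_cost`, `offset`.
#' @export
build_design <- function(cohort, features, offset = 1) {
  check_number(offset, "offset", min = 0)
  if (any(cohort$observed_cost < 0)) abort("observed_cost must be >= 0.")
  feat <- features[match(cohort$id, features$id), , drop = FALSE]
  if (anyNA(feat$id)) abort("`features` is missing rows for some beneficiaries.")
  fm <- as.matrix(feat[, setdiff(names(feat), "id"), drop = FALSE])
  x <- cbind(age = cohort$age, male = as.numeric(cohort$sex == "M"), fm)
  rownames(x) <- cohort$id
  structure(
    list(
      x = x,
      y = log(cohort$observed_cost + offset),
      ids = cohort$id,
      observed_cost = cohort$observed_cost,
      offset = offset
    ),
    class = "franklin_design"
  )
}

#' Default boosted-tree hyperparameters
#'
#' Conventional settings for a medium-width tabular regression: 500 trees
#' of depth 6, learning rate 0.05, 80% row subsampling, early stopping
#' after 20 rounds without validation improvement. All overridable.
#'
#' @param nrounds,max_depth,eta,subsample,early_stopping_rounds,nthread,seed
#'   Standard xgboost controls.
#' @return A named list.
#' @export
risk_model_params <- function(nrounds = 500L, max_depth = 6L, eta = 0.05,
                              subsample = 0.8, early_stopping_rounds = 20L,
                              nthread = 1L, seed = 1L) {
  list(nrounds = nrounds, max_depth = max_depth, eta = eta,
       subsample = subsample,
       early_stopping_rounds = early_stopping_rounds,
       nthread = nthread, seed = seed)
}

#' Fit the boosted log-cost risk model
#'
#' Gradient-boosted regression trees minimizing squared error on
#' `log(cost + c)`, with early stopping on validation loss. Deterministic
#' for a fixed seed.
#'
#' @param train A `franklin_design` for the training split.
#' @param validation A `franklin_design` for the validation split (used for
#'   early stopping / tuning), or `NULL` to train for the full `nrounds`.
#' @param params Hyperparameters from [risk_model_params()].
#' @param embeddings,clusters Optionally, the fitted upstream models the
#'   design depends on (stored in the bundle for provenance).
#' @return A list of class `franklin_risk_model` with the fitted `booster`,
#'   `params`, `offset`, `feature_names`, `best_iteration`, optional
#'   `calibration` (see [calibrate_deciles()]) and the upstream model
#'   references.
#' @export
fit_risk_model <- function(train, validation = NULL,
                           params = risk_model_params(),
                           embeddings = NULL, clusters = NULL) {
  stopifnot(inherits(train, "franklin_design"))
  if (nrow(train$x) == 0) abort("training design is empty.")
  if (!is.null(validation)) {
    stopifnot(inherits(validation, "franklin_design"))
    if (length(intersect(train$ids, validation$ids)) > 0) {
      abort("train and validation beneficiaries must be disjoint.")
    }
  }
  dtrain <- xgboost::xgb.DMatrix(train$x, label = train$y, nthread = params$nthread)
  evals <- list()
  if (!is.null(validation)) {
    evals <- list(validation = xgboost::xgb.DMatrix(
      validation$x, label = validation$y, nthread = params$nthread))
  }
  booster <- xgboost::xgb.train(
    params = xgboost::xgb.params(
      objective = "reg:squarederror",
      max_depth = params$max_depth,
      eta = params$eta,
      subsample = params$subsample,
      nthread = params$nthread,
      seed = params$seed
    ),
    data = dtrain,
    nrounds = params$nrounds,
    evals = evals,
    early_stopping_rounds = if (length(evals)) params$early_stopping_rounds else NULL,
    verbose = 0
  )
  best <- tryCatch(xgboost::xgb.attr(booster, "best_iteration"),
                   error = function(e) NULL)
  structure(
    list(
      booster = booster,
      params = params,
      offset = train$offset,
      feature_names = colnames(train$x),
      best_iteration = if (is.null(best)) params$nrounds else as.integer(best),
      calibration = NULL,
      embeddings = embeddings,
      clusters = clusters
    ),
    class = "franklin_risk_model"
  )
}

#' Predict log cost for a design
#'
#' @param model A `franklin_risk_model`.
#' @param design A `franklin_design` (or bare numeric matrix with the same
#'   columns as the training design).
#' @return Numeric vector of predicted `log(cost + c)`, one per row.
#' @export
predict_log_cost <- function(model, design) {
  stopifnot(inherits(model, "franklin_risk_model"))
  x <- if (inherits(design, "franklin_design")) design$x else design
  if (!identical(colnames(x), model$feature_names)) {
    abort("design columns do not match the fitted model's features.")
  }
  as.numeric(predict(
    model$booster,
    xgboost::xgb.DMatrix(x, nthread = model$params$nthread)
  ))
}

#' Calibrate predictive ratios to 1 within predicted-risk deciles
#'
#' Beneficiaries are ranked by predicted cost into 10 equal-count deciles
#' (ties broken stably by input order); each decile's multiplicative factor
#' is mean observed over mean predicted cost. Applying the table to the
#' calibration set makes every decile's predictive ratio exactly 1 and
#' conserves total dollars.
#'
#' @param predicted_cost,observed_cost Paired cost-scale vectors
#'   (length >= 10).
#' @return A tibble of class `franklin_calibration` with columns `decile`,
#'   `upper` (decile boundary on the predicted-cost scale), `factor`, `n`,
#'   `mean_predicted`, `mean_observed`.
#' @export
calibrate_deciles <- function(predicted_cost, observed_cost) {
  check_paired(predicted_cost, observed_cost, min_length = 10L)
  dec <- decile_assignment(predicted_cost)
  tab <- purrr::map_dfr(1:10, function(d) {
    idx <- dec == d
    mp <- mean(predicted_cost[idx])
    if (mp == 0) abort(sprintf("decile %d has mean predicted cost 0.", d))
    tibble(
      decile = d,
      upper = max(predicted_cost[idx]),
      factor = mean(observed_cost[idx]) / mp,
      n = sum(idx),
      mean_predicted = mp,
      mean_observed = mean(observed_cost[idx])
    )
  })
  class(tab) <- c("franklin_calibration", class(tab))
  tab
}

#' Apply a decile calibration table to cost-scale predictions
#'
#' New predictions are binned by the calibration deciles' upper boundaries
#' (values beyond the last boundary fall in the top decile) and multiplied
#' by the decile factor.
#'
#' @param calibration A `franklin_calibration`.
#' @param predicted_cost Cost-scale predictions.
#' @return Calibrated predictions.
#' @export
apply_calibration <- function(calibration, predicted_cost) {
  stopifnot(inherits(calibration, "franklin_calibration"))
  breaks <- calibration$upper[1:9]
  dec <- findInterval(predicted_cost, breaks, left.open = TRUE) + 1L
  predicted_cost * calibration$factor[dec]
}

#' Cost-scale predictions from the risk model
#'
#' Retransforms predicted log cost to dollars (`exp(pred) - c`), floors at
#' a small positive payment floor, and applies decile calibration factors
#' when available. Decile calibration absorbs the retransformation bias
#' that exponentiating log-scale predictions would otherwise leave.
#'
#' @param model A `franklin_risk_model`.
#' @param design A `franklin_design`.
#' @param calibration Optional `franklin_calibration`; defaults to the one
#'   stored in the model bundle (if any).
#' @param floor Payment floor in USD.
#' @return Numeric vector of predicted USD.
#' @export
predict_cost <- function(model, design, calibration = model$calibration,
                         floor = 1) {
  raw <- pmax(exp(predict_log_cost(model, design)) - model$offset, floor)
  if (!is.null(calibration)) raw <- apply_calibration(calibration, raw)
  raw
}

#' Log-scale recalibration of a cost-scale baseline
#'
#' HCC-style baselines predict dollars directly; to evaluate them against
#' log cost, an ordinary least-squares map
#' `log(cost + c) ~ log(predicted + c)` is fitted on a calibration split
#' and applied out-of-sample. Monotone, two-parameter and rank-preserving.
#'
#' @param predicted_cost,observed_cost Paired cost-scale vectors from the
#'   calibration split.
#' @param offset Log offset `c` (USD).
#' @return A list of class `franklin_log_recalibration` with `intercept`,
#'   `slope`, `offset`.
#' @export
fit_log_recalibration <- function(predicted_cost, observed_cost, offset = 1) {
  check_paired(predicted_cost, observed_cost, min_length = 3L)
  xp <- log(predicted_cost + offset)
  y <- log(observed_cost + offset)
  fit <- lm(y ~ xp)
  structure(
    list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
         offset = offset),
    class = "franklin_log_recalibration"
  )
}

#' @rdname fit_log_recalibration
#' @param recal A `franklin_log_recalibration`.
#' @param predicted_cost Cost-scale predictions to map onto the log scale.
#' @return Predicted `log(cost + c)`.
#' @export
apply_log_recalibration <- function(recal, predicted_cost) {
  stopifnot(inherits(recal, "franklin_log_recalibration"))
  recal$intercept + recal$slope * log(predicted_cost + recal$offset)
}
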