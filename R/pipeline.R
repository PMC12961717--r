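# End-to-end demo pipeline: generate a synthetic cohort, split it, train
# the embedding-cluster risk model and an HCC-style baseline with partial
# category coverage, evaluate both on the test split, and run the
# favorable-selection simulation.

#' Configuration for the demo pipeline
#'
#' Every field has a documented default; unknown keys are rejected. The
#' defaults define a cohort large enough for the embedding and boosting
#' stages to be well-conditioned while staying desk-scale.
#'
#' @param n_beneficiaries Cohort size.
#' @param n_conditions Latent conditions (K).
#' @param vocab_size,codes_per_condition,residual_log_sd,zero_dx_fraction
#'   Generator settings (see [generator_config()]).
#' @param split_fractions Four split fractions
#'   (embeddings/training/validation/test).
#' @param embedding_d Embedding dimension.
#' @param cluster_k Number of clusters.
#' @param min_count Vocabulary floor for the co-occurrence matrix.
#' @param offset Log offset `c` in USD.
#' @param model_params Hyperparameters from [risk_model_params()].
#' @param baseline_conditions Which latent conditions the baseline category
#'   map covers (indices); partial coverage mirrors the gap between
#'   category-based scoring and full-profile scoring.
#' @param q Classification tail quantile.
#' @param error_thresholds Percentile-error thresholds.
#' @param n_boot Bootstrap replicates for decile CIs.
#' @param tau_grid Selection strengths for the simulation.
#' @param plan_size,n_selection_samples Selection-simulation scale.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A validated list of class `franklin_run_config`.
#' @export
demo_config <- function(n_beneficiaries = 20000,
                        n_conditions = 10,
                        vocab_size = 400,
                        codes_per_condition = 10,
                        residual_log_sd = 1.0,
                        zero_dx_fraction = 0.05,
                        split_fractions = c(0.2, 0.4, 0.2, 0.2),
                        embedding_d = 50,
                        cluster_k = 250,
                        min_count = 5,
                        offset = 1,
                        model_params = risk_model_params(),
                        baseline_conditions = NULL,
                        q = 0.20,
                        error_thresholds = c(20, 40),
                        n_boot = 100,
                        tau_grid = c(0.1, 0.3, 0.5),
                        plan_size = 5000,
                        n_selection_samples = 500,
                        seed = 1L) {
  cfg <- list(
    n_beneficiaries = n_beneficiaries, n_conditions = n_conditions,
    vocab_size = vocab_size, codes_per_condition = codes_per_condition,
    residual_log_sd = residual_log_sd, zero_dx_fraction = zero_dx_fraction,
    split_fractions = split_fractions, embedding_d = embedding_d,
    cluster_k = cluster_k, min_count = min_count, offset = offset,
    model_params = model_params, baseline_conditions = baseline_conditions,
    q = q, error_thresholds = error_thresholds, n_boot = n_boot,
    tau_grid = tau_grid, plan_size = plan_size,
    n_selection_samples = n_selection_samples, seed = as.integer(seed)
  )
  validate_run_config(cfg)
}

#' @rdname demo_config
#' @param config A named list of overrides (e.g. parsed from a flat YAML
#'   config file); unknown keys raise an error.
#' @export
as_run_config <- function(config) {
  defaults <- formals(demo_config)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(demo_config, config)
}

validate_run_config <- function(cfg) {
  check_number(cfg$n_beneficiaries, "n_beneficiaries", min = 100, integerish = TRUE)
  check_number(cfg$n_conditions, "n_conditions", min = 2, integerish = TRUE)
  if (length(cfg$split_fractions) != 4 ||
      abs(sum(cfg$split_fractions) - 1) > 1e-9) {
    abort("`split_fractions` must be 4 probabilities summing to 1.")
  }
  check_number(cfg$embedding_d, "embedding_d", min = 2, integerish = TRUE)
  check_number(cfg$cluster_k, "cluster_k", min = 2, integerish = TRUE)
  check_number(cfg$offset, "offset", min = 0)
  check_number(cfg$q, "q", min = 1e-6, max = 0.5 - 1e-6)
  check_number(cfg$plan_size, "plan_size", min = 10, integerish = TRUE)
  if (is.null(cfg$baseline_conditions)) {
    cfg$baseline_conditions <- seq_len(ceiling(cfg$n_conditions / 2))
  }
  if (any(cfg$baseline_conditions < 1 | cfg$baseline_conditions > cfg$n_conditions)) {
    abort("`baseline_conditions` must index existing conditions.")
  }
  structure(cfg, class = "franklin_run_config")
}

#' HCC-style category map derived from generator ground truth
#'
#' Builds a toy but principled category map covering a subset of the
#' latent conditions: one category per covered condition, mapped from that
#' condition's codes; weights fitted by least squares of relative cost
#' (cost / base cost) on category indicators plus demographic cells, with
#' negative weights clipped to zero (the baseline only admits nonnegative
#' weights, so cost-lowering conditions are scored as zero).
#'
#' @param sim A `franklin_cohort_sim` from [generate_cohort()].
#' @param conditions Indices of the latent conditions to cover.
#' @param fit_ids Optionally, beneficiary ids to fit the weights on
#'   (e.g. the training split); defaults to the full cohort.
#' @return A `franklin_category_map`.
#' @export
demo_category_map <- function(sim, conditions = NULL, fit_ids = NULL) {
  stopifnot(inherits(sim, "franklin_cohort_sim"))
  K <- sim$ground_truth$config$n_conditions
  if (is.null(conditions)) conditions <- seq_len(ceiling(K / 2))
  cohort <- sim$cohort
  if (!is.null(fit_ids)) cohort <- cohort[cohort$id %in% fit_ids, , drop = FALSE]
  base_cost <- mean(cohort$observed_cost)

  cc <- sim$ground_truth$code_conditions
  cc <- cc[cc$condition %in% conditions, , drop = FALSE]
  mappings <- tibble(code = cc$code, category = sprintf("HCC%02d", cc$condition))
  cat_ids <- sort(unique(mappings$category))

  # Category presence via mapped codes (the same path the scorer uses).
  dx <- sim$diagnoses[sim$diagnoses$id %in% cohort$id, , drop = FALSE]
  dx <- dx[dx$code %in% mappings$code, , drop = FALSE]
  dx$category <- mappings$category[match(dx$code, mappings$code)]
  ind <- matrix(0, nrow = nrow(cohort), ncol = length(cat_ids),
                dimnames = list(cohort$id, cat_ids))
  if (nrow(dx) > 0) {
    pairs <- unique(dx[, c("id", "category")])
    ind[cbind(match(pairs$id, cohort$id), match(pairs$category, cat_ids))] <- 1
  }

  band <- pmin(cohort$age - ((cohort$age - 65) %% 5), 90)  # 5-year bands, 90+
  cell <- interaction(band, cohort$sex, drop = FALSE)
  fit <- lm(cohort$observed_cost / base_cost ~ 0 + cell + ind)
  cf <- coef(fit)
  cf[is.na(cf)] <- 0
  cell_w <- pmax(cf[startsWith(names(cf), "cell")], 0.01)
  cat_w <- pmax(cf[paste0("ind", cat_ids)], 0)

  cells_tbl <- purrr::map_dfr(levels(cell), function(l) {
    parts <- strsplit(l, ".", fixed = TRUE)[[1]]
    lo <- as.integer(parts[1])
    tibble(age_min = lo, age_max = if (lo >= 90) 130L else lo + 4L,
           sex = parts[2],
           weight = unname(cell_w[paste0("cell", l)]))
  })
  category_map(
    categories = tibble(category = cat_ids, weight = unname(cat_w)),
    mappings = mappings,
    cells = cells_tbl,
    base_cost = base_cost
  )
}

#' Run the full demonstration pipeline
#'
#' Generates a synthetic cohort, performs the four-way split, learns
#' embeddings on the embeddings split, clusters them, trains the boosted
#' log-cost model on the training split with early stopping on the
#' validation split, decile-calibrates cost-scale predictions on the
#' validation split, scores the HCC-style baseline (covering only the
#' configured subset of conditions), evaluates both models on the test
#' split, and runs the favorable-selection simulation on the test split
#' with both payment models recalibrated there (cohort predictive ratio 1).
#'
#' @param config A [demo_config()] (or list coercible via
#'   [as_run_config()]).
#' @param dry_run If `TRUE`, validate the configuration and return it
#'   without computing.
#' @param out_dir Optional directory; when given, the evaluation report is
#'   written as `report.json` plus CSV tables.
#' @param verbose Log stage boundaries to `stderr`.
#' @return A list of class `franklin_demo` with the fitted objects, both
#'   evaluations, the selection results and a `report` list of plain
#'   values.
#' @export
run_demo <- function(config = demo_config(), dry_run = FALSE, out_dir = NULL,
                     verbose = FALSE) {
  if (!inherits(config, "franklin_run_config")) config <- as_run_config(config)
  if (dry_run) return(config)
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed

  say("[generate] n=%d, K=%d, seed=%d", config$n_beneficiaries,
      config$n_conditions, seed)
  sim <- generate_cohort(generator_config(
    n_beneficiaries = config$n_beneficiaries,
    n_conditions = config$n_conditions,
    vocab_size = config$vocab_size,
    codes_per_condition = config$codes_per_condition,
    residual_log_sd = config$residual_log_sd,
    zero_dx_fraction = config$zero_dx_fraction,
    seed = seed
  ))
  cohort <- split_cohort(sim$cohort, seed = seed + 1L)
  parts <- split(cohort, cohort$split)
  dx_of <- function(part) {
    sim$diagnoses[sim$diagnoses$id %in% part$id, , drop = FALSE]
  }

  say("[embed] embeddings split n=%d", nrow(parts$embeddings))
  cooc <- build_cooccurrence(dx_of(parts$embeddings), min_count = config$min_count)
  emb <- suppressWarnings(train_embeddings(cooc, d = config$embedding_d))
  say("[cluster] vocabulary=%d, k=%d", length(cooc$vocabulary), config$cluster_k)
  clusters <- suppressWarnings(fit_clusters(emb, k = config$cluster_k,
                                            seed = seed + 2L))

  say("[features] computing cluster features for %d beneficiaries", nrow(cohort))
  features <- compute_cluster_features(cohort, sim$diagnoses, emb, clusters)
  design_of <- function(part) {
    build_design(part, features[match(part$id, features$id), , drop = FALSE],
                 offset = config$offset)
  }
  d_train <- design_of(parts$training)
  d_valid <- design_of(parts$validation)
  d_test <- design_of(parts$test)

  say("[train] boosting on %d rows", nrow(d_train$x))
  params <- config$model_params
  params$seed <- seed + 3L
  model <- fit_risk_model(d_train, d_valid, params = params,
                          embeddings = emb, clusters = clusters)
  model$calibration <- calibrate_deciles(
    predict_cost(model, d_valid, calibration = NULL),
    parts$validation$observed_cost
  )
  franklin_cost_test <- predict_cost(model, d_test)

  say("[baseline] HCC-style map over conditions %s",
      paste(config$baseline_conditions, collapse = ","))
  map <- demo_category_map(sim, conditions = config$baseline_conditions,
                           fit_ids = parts$training$id)
  hcc_all <- hcc_score(cohort, sim$diagnoses, map)
  hcc_cost <- setNames(hcc_all$predicted_cost, hcc_all$id)
  hcc_cal <- calibrate_deciles(hcc_cost[parts$validation$id],
                               parts$validation$observed_cost)
  hcc_cost_test <- apply_calibration(hcc_cal, hcc_cost[parts$test$id])
  # Log-scale recalibration of the baseline, fitted on the training split.
  hcc_recal <- fit_log_recalibration(hcc_cost[parts$training$id],
                                     parts$training$observed_cost,
                                     offset = config$offset)

  say("[evaluate] test split n=%d", nrow(parts$test))
  obs_test <- parts$test$observed_cost
  eval_franklin <- evaluate_model(
    franklin_cost_test, obs_test, data = parts$test,
    subgroups = intersect("region", names(parts$test)),
    q = config$q, thresholds = config$error_thresholds,
    n_boot = config$n_boot, seed = seed + 4L, offset = config$offset
  )
  # The boosted model's native output is predicted log cost: its log-scale
  # fit is scored on that output directly (cost-scale predictions, which
  # fold in decile calibration, drive the dollar/rank/distribution metrics).
  franklin_log_test <- predict_log_cost(model, d_test)
  eval_franklin$fit$r2_log <- r_squared(franklin_log_test,
                                        log(obs_test + config$offset))
  eval_franklin$dispersion <- dispersion_decomposition(
    obs_test, r2_log = eval_franklin$fit$r2_log, offset = config$offset
  )
  eval_hcc <- evaluate_model(
    hcc_cost_test, obs_test, data = parts$test,
    subgroups = intersect("region", names(parts$test)),
    q = config$q, thresholds = config$error_thresholds,
    n_boot = config$n_boot, seed = seed + 4L, offset = config$offset
  )
  # The baseline's log-scale fit uses its recalibrated log predictions.
  hcc_log_pred <- apply_log_recalibration(hcc_recal, hcc_cost[parts$test$id])
  eval_hcc$fit$r2_log <- r_squared(hcc_log_pred,
                                   log(obs_test + config$offset))
  eval_hcc$dispersion <- dispersion_decomposition(
    obs_test, r2_log = eval_hcc$fit$r2_log, offset = config$offset
  )

  tt <- downsampled_ttest(franklin_cost_test, hcc_cost_test, obs_test,
                          metric = "spearman_rho", seed = seed + 5L,
                          sample_size = min(1000L, nrow(parts$test)),
                          offset = config$offset)

  say("[simulate] tau grid {%s}", paste(config$tau_grid, collapse = ", "))
  # Payments for the simulation: recalibrated on the simulation cohort so
  # the cohort-level predictive ratio is 1 for both models.
  pay_franklin <- apply_calibration(
    calibrate_deciles(franklin_cost_test, obs_test), franklin_cost_test)
  pay_hcc <- apply_calibration(
    calibrate_deciles(hcc_cost_test, obs_test), hcc_cost_test)
  selection <- overpayment_curve(
    obs_test,
    payments = list(franklin = pay_franklin, hcc = pay_hcc),
    tau_grid = config$tau_grid,
    plan_size = min(config$plan_size, nrow(parts$test)),
    n_samples = config$n_selection_samples,
    seed = seed + 6L
  )

  report <- list(
    config = unclass(config)[setdiff(names(config), "model_params")],
    seed = seed,
    splits = as.list(table(cohort$split)),
    vocabulary_size = length(cooc$vocabulary),
    franklin = as.list(eval_franklin$fit),
    hcc = as.list(eval_hcc$fit),
    downsampled_ttest = as.list(tt),
    selection = purrr::map(split(selection, seq_len(nrow(selection))), as.list)
  )

  out <- structure(
    list(
      sim = sim, cohort = cohort, embeddings = emb, clusters = clusters,
      model = model, category_map = map,
      evaluation = list(franklin = eval_franklin, hcc = eval_hcc),
      downsampled_ttest = tt,
      selection = selection,
      predictions = tibble(
        id = parts$test$id,
        observed_cost = obs_test,
        franklin_cost = franklin_cost_test,
        hcc_cost = as.numeric(hcc_cost_test)
      ),
      report = report
    ),
    class = "franklin_demo"
  )
  if (!is.null(out_dir)) write_demo_report(out, out_dir)
  out
}

#' @export
print.franklin_demo <- function(x, ...) {
  cat("<franklin_demo>\n  fit (test split):\n")
  fit <- dplyr::bind_rows(
    dplyr::mutate(x$evaluation$franklin$fit, model = "franklin"),
    dplyr::mutate(x$evaluation$hcc$fit, model = "hcc")
  )
  print(dplyr::select(fit, "model", dplyr::everything()))
  invisible(x)
}

write_demo_report <- function(demo, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(demo$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(demo$predictions, file.path(out_dir, "predictions.csv"),
                   progress = FALSE)
  readr::write_csv(demo$selection, file.path(out_dir, "selection.csv"),
                   progress = FALSE)
  readr::write_csv(demo$evaluation$franklin$deciles,
                   file.path(out_dir, "deciles_franklin.csv"), progress = FALSE)
  readr::write_csv(demo$evaluation$hcc$deciles,
                   file.path(out_dir, "deciles_hcc.csv"), progress = FALSE)
  invisible(out_dir)
}
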