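# Accuracy, classification, error-frequency, actuarial-dispersion and
# subgroup metrics for cost-scale predictions, plus the downsampled
# significance test and the predictive-ratio variance decomposition.

#' Statistical fit metrics for cost predictions
#'
#' Computes, on paired cost-scale vectors:
#' * `r2_log` — R-squared between `log(pred + c)` and `log(obs + c)`
#'   (1 - SSE/SST);
#' * `r2_cost` — R-squared on the raw cost scale;
#' * `mae_cost` — mean absolute error in USD;
#' * `spearman_rho` — rank correlation (average-rank ties);
#' * `ks_log` — two-sample Kolmogorov-Smirnov sup-distance between the
#'   empirical distributions of predicted and observed log costs (lower is
#'   better distributional alignment).
#'
#' @param predicted,observed Paired cost-scale vectors (length >= 3).
#' @param offset Log offset `c` (USD).
#' @return A one-row tibble with the five metrics and `n`.
#' @export
compute_fit_metrics <- function(predicted, observed, offset = 1) {
  check_paired(predicted, observed, min_length = 3L)
  lp <- log(predicted + offset)
  lo <- log(observed + offset)
  tibble(
    n = length(observed),
    r2_log = r_squared(lp, lo),
    r2_cost = r_squared(predicted, observed),
    mae_cost = mean(abs(predicted - observed)),
    spearman_rho = suppressWarnings(cor(predicted, observed, method = "spearman")),
    ks_log = ks_statistic(lp, lo)
  )
}

# 1 - SSE/SST of `pred` as a prediction of `obs`.
r_squared <- function(pred, obs) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}

#' Extreme-cost classification metrics
#'
#' Treats membership in the lowest (or highest) `q`-tail of the actual cost
#' distribution as the positive class, and the same-`q` tail of the
#' predicted distribution as the predicted positives (tail sizes are equal
#' by construction, ties broken stably by input order, so sensitivity
#' equals precision).
#'
#' @param predicted,observed Paired cost-scale vectors.
#' @param q Tail quantile, strictly between 0 and 0.5 (default 0.20).
#' @param tails Which tails to evaluate (default both).
#' @return Tibble with one row per tail: `tail`, `q`, `cost_threshold`
#'   (actual-cost boundary of the tail), `sensitivity`, `specificity`,
#'   `precision`.
#' @export
classify_extremes <- function(predicted, observed, q = 0.20,
                              tails = c("low", "high")) {
  check_paired(predicted, observed, min_length = 2L)
  if (!(q > 0 && q < 0.5)) abort("`q` must satisfy 0 < q < 0.5.")
  tails <- match.arg(tails, c("low", "high"), several.ok = TRUE)
  n <- length(observed)
  m <- max(1L, round(q * n))
  purrr::map_dfr(tails, function(tail) {
    sgn <- if (tail == "low") 1 else -1
    actual_pos <- seq_len(n) %in% order(sgn * observed, seq_len(n))[seq_len(m)]
    pred_pos <- seq_len(n) %in% order(sgn * predicted, seq_len(n))[seq_len(m)]
    tp <- sum(actual_pos & pred_pos)
    tn <- sum(!actual_pos & !pred_pos)
    thr <- if (tail == "low") max(observed[actual_pos]) else min(observed[actual_pos])
    tibble(
      tail = tail, q = q, cost_threshold = thr,
      sensitivity = tp / m,
      specificity = tn / (n - m),
      precision = tp / m
    )
  })
}

#' Frequencies of substantial prediction errors
#'
#' A beneficiary's prediction error is their percentile rank by predicted
#' cost minus their percentile rank by observed cost (average-rank ties,
#' 0-100 scale, ranks computed within the evaluation cohort). Reports the
#' share of beneficiaries overpredicted (error >= t) and underpredicted
#' (error <= -t) at each threshold.
#'
#' @param predicted,observed Paired cost-scale vectors.
#' @param thresholds Percentile-point thresholds (default 20 and 40).
#' @param full_curve If `TRUE`, also evaluate every integer threshold
#'   0..100.
#' @return Tibble with `threshold`, `overprediction`, `underprediction`.
#' @export
prediction_error_frequencies <- function(predicted, observed,
                                         thresholds = c(20, 40),
                                         full_curve = FALSE) {
  check_paired(predicted, observed)
  n <- length(observed)
  err <- (rank(predicted, ties.method = "average") -
            rank(observed, ties.method = "average")) / n * 100
  if (full_curve) thresholds <- sort(unique(c(thresholds, 0:100)))
  purrr::map_dfr(thresholds, function(t) {
    tibble(
      threshold = t,
      overprediction = mean(err >= t),
      underprediction = mean(err <= -t)
    )
  })
}

#' Predictive ratio and observed-cost dispersion by risk decile
#'
#' Beneficiaries are split into 10 equal-count deciles by predicted cost.
#' Per decile: predictive ratio (mean predicted / mean observed), the IQR
#' of observed cost, and the decile range (90th minus 10th percentile of
#' observed cost), each with percentile-bootstrap confidence intervals
#' over beneficiary resampling within the decile.
#'
#' @param predicted,observed Paired cost-scale vectors.
#' @param n_boot Bootstrap replicates (0 skips the CIs).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level.
#' @return Tibble with one row per decile.
#' @export
decile_dispersion <- function(predicted, observed, n_boot = 200L, seed = 1L,
                              conf = 0.95) {
  check_paired(predicted, observed, min_length = 10L)
  dec <- decile_assignment(predicted)
  alpha <- (1 - conf) / 2
  with_seed(seed, purrr::map_dfr(1:10, function(d) {
    obs <- observed[dec == d]
    prd <- predicted[dec == d]
    stat <- function(o, p) {
      qs <- quantile(o, c(0.1, 0.25, 0.75, 0.9), names = FALSE)
      c(pr = mean(p) / mean(o), iqr = qs[3] - qs[2], range = qs[4] - qs[1])
    }
    est <- stat(obs, prd)
    row <- tibble(
      decile = d, n = length(obs),
      predictive_ratio = est[["pr"]],
      iqr = est[["iqr"]],
      decile_range = est[["range"]]
    )
    if (n_boot > 0) {
      boot <- replicate(n_boot, {
        idx <- sample.int(length(obs), replace = TRUE)
        stat(obs[idx], prd[idx])
      })
      ci <- apply(boot, 1, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
      row$pr_lo <- ci[1, "pr"]; row$pr_hi <- ci[2, "pr"]
      row$iqr_lo <- ci[1, "iqr"]; row$iqr_hi <- ci[2, "iqr"]
      row$range_lo <- ci[1, "range"]; row$range_hi <- ci[2, "range"]
    }
    row
  }))
}

#' Structural and residual dispersion factors of the predictive ratio
#'
#' For log-normal costs with log-scale SD `sigma`, the variability of a
#' plan-level predictive ratio decomposes into a model-independent
#' structural factor `exp(sigma^2 / 2)` (actuarial exposure from cost
#' outliers) and a residual factor `exp((1 - r2_log) * sigma^2) - 1` that a
#' better risk model (higher R-squared of log cost) shrinks. The ratio of
#' residual factors between two models predicts the ratio of their
#' plan-level predictive-ratio variances (see [pr_variance_simulation()]).
#'
#' @param observed Observed costs (used to estimate `sigma` as the sample
#'   SD of `log(cost + offset)`), or `NULL` if `sigma` is given directly.
#' @param r2_log Log-scale R-squared of the model under study.
#' @param offset Log offset `c` (USD).
#' @param sigma Optional log-scale SD, overriding estimation.
#' @return One-row tibble with `sigma`, `r2_log`, `structural_factor`,
#'   `residual_factor`.
#' @export
dispersion_decomposition <- function(observed = NULL, r2_log, offset = 1,
                                     sigma = NULL) {
  if (is.null(sigma)) {
    if (is.null(observed)) abort("supply `observed` costs or `sigma`.")
    sigma <- sd(log(observed + offset))
    if (is.na(sigma)) sigma <- 0
  }
  check_number(sigma, "sigma", min = 0)
  check_number(r2_log, "r2_log", max = 1)
  tibble(
    sigma = sigma,
    r2_log = r2_log,
    structural_factor = exp(sigma^2 / 2),
    residual_factor = exp((1 - r2_log) * sigma^2) - 1
  )
}

#' Monte-Carlo check of the predictive-ratio variance decomposition
#'
#' Simulates log-normal costs (`log cost ~ N(0, sigma^2)`) and, for each
#' requested `r2_log`, a Gaussian log-scale predictor equal to the true log
#' cost plus independent noise of variance `(1 - r2_log) * sigma^2`, with
#' payments the mean-calibrated exponentiated predictions. Draws
#' `n_plans` independent plans of `plan_size` members and records the
#' empirical variance of the plan-level predictive ratio. Common random
#' numbers are used across models so variance ratios are tightly
#' estimated.
#'
#' @param sigma Log-scale cost SD.
#' @param r2_log Vector of log-scale R-squared values to simulate.
#' @param plan_size Members per plan.
#' @param n_plans Number of simulated plans (>= 2).
#' @param seed Integer seed.
#' @return Tibble with one row per `r2_log`: `var_pr` (empirical variance
#'   of the plan predictive ratio), `residual_factor`, and
#'   `scaled_var` (= `plan_size * var_pr / exp(sigma^2)`, comparable to the
#'   residual factor).
#' @export
pr_variance_simulation <- function(sigma = 1.2, r2_log = c(0.15, 0.44),
                                   plan_size = 1000L, n_plans = 2000L,
                                   seed = 1L) {
  check_number(sigma, "sigma", min = 0)
  check_number(plan_size, "plan_size", min = 2, integerish = TRUE)
  check_number(n_plans, "n_plans", min = 2, integerish = TRUE)
  pr <- matrix(NA_real_, nrow = n_plans, ncol = length(r2_log))
  with_seed(seed, {
    for (p in seq_len(n_plans)) {
      y <- rnorm(plan_size, 0, sigma)
      w0 <- rnorm(plan_size)
      obs <- exp(y)
      for (j in seq_along(r2_log)) {
        tau2 <- (1 - r2_log[j]) * sigma^2
        pred <- exp(y + sqrt(tau2) * w0 - tau2 / 2)
        pr[p, j] <- sum(pred) / sum(obs)
      }
    }
  })
  tibble(
    r2_log = r2_log,
    var_pr = apply(pr, 2, var),
    residual_factor = exp((1 - r2_log) * sigma^2) - 1,
    scaled_var = plan_size * apply(pr, 2, var) / exp(sigma^2)
  )
}

#' Downsampled paired significance test between two models
#'
#' Compares a fit metric between two prediction vectors on repeated small
#' samples — by default 100 samples of 1000 beneficiaries — and runs a
#' paired two-sided t-test on the per-sample metric differences.
#' Downsampling avoids the overstated significance that tiny metric
#' differences attain at full cohort size.
#'
#' @param predicted_a,predicted_b Cost-scale predictions of the two models.
#' @param observed Observed costs.
#' @param metric One of `"r2_log"`, `"r2_cost"`, `"mae_cost"`,
#'   `"spearman_rho"`, `"ks_log"`.
#' @param n_samples Number of samples (default 100).
#' @param sample_size Beneficiaries per sample (default 1000).
#' @param replace Sample with replacement (default); set `FALSE` for
#'   disjoint-leaning subsampling without replacement per sample.
#' @param seed Integer seed.
#' @param offset Log offset `c`.
#' @return A one-row tibble: `metric`, `mean_difference` (A minus B),
#'   `statistic`, `p_value`, `n_samples`, `sample_size`.
#' @export
downsampled_ttest <- function(predicted_a, predicted_b, observed,
                              metric = "r2_log", n_samples = 100L,
                              sample_size = 1000L, replace = TRUE,
                              seed = 1L, offset = 1) {
  check_paired(predicted_a, observed)
  check_paired(predicted_b, observed)
  metric <- match.arg(metric,
                      c("r2_log", "r2_cost", "mae_cost", "spearman_rho", "ks_log"))
  n <- length(observed)
  if (!replace && sample_size > n) {
    abort("sample_size exceeds cohort size for without-replacement sampling.")
  }
  one <- function(pred, idx) {
    compute_fit_metrics(pred[idx], observed[idx], offset = offset)[[metric]]
  }
  diffs <- with_seed(seed, vapply(seq_len(n_samples), function(s) {
    for (attempt in 1:2) {
      idx <- sample.int(n, sample_size, replace = replace)
      d <- one(predicted_a, idx) - one(predicted_b, idx)
      if (is.finite(d)) return(d)
    }
    abort("metric undefined on a redrawn sample.")
  }, numeric(1)))
  if (all(diffs == 0)) {
    return(tibble(metric = metric, mean_difference = 0,
                  statistic = NA_real_, p_value = 1,
                  n_samples = n_samples, sample_size = sample_size))
  }
  tt <- t.test(diffs)
  tibble(
    metric = metric,
    mean_difference = mean(diffs),
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    n_samples = n_samples,
    sample_size = sample_size
  )
}

#' Fit metrics within subgroups
#'
#' Computes [compute_fit_metrics()] per level of a subgroup column. Levels
#' smaller than `min_size` are flagged (not dropped).
#'
#' @param data Tibble holding the subgroup column, one row per beneficiary
#'   in the same order as the prediction vectors.
#' @param predicted,observed Paired cost-scale vectors.
#' @param subgroup Name of the subgroup column in `data`.
#' @param min_size Minimum level size below which the level is flagged.
#' @param offset Log offset `c`.
#' @return Tibble with one row per level: `level`, `n`, `share`,
#'   `flagged`, and the fit metric columns.
#' @export
subgroup_evaluate <- function(data, predicted, observed, subgroup,
                              min_size = 30L, offset = 1) {
  if (!subgroup %in% names(data)) {
    abort(sprintf("unknown subgroup column `%s`.", subgroup))
  }
  check_paired(predicted, observed)
  if (nrow(data) != length(observed)) {
    abort("`data` must have one row per prediction.")
  }
  lev <- as.character(data[[subgroup]])
  purrr::map_dfr(sort(unique(lev)), function(l) {
    idx <- lev == l
    m <- compute_fit_metrics(predicted[idx], observed[idx], offset = offset)
    dplyr::bind_cols(
      tibble(level = l, n = sum(idx), share = mean(idx),
             flagged = sum(idx) < min_size),
      m[, setdiff(names(m), "n")]
    )
  })
}

#' Full evaluation report for one model on one cohort
#'
#' Bundles fit metrics, extreme-cost classification, prediction-error
#' frequencies, decile dispersion and the dispersion decomposition.
#'
#' @param predicted,observed Paired cost-scale vectors.
#' @param data Optional tibble with subgroup columns.
#' @param subgroups Character vector of subgroup column names.
#' @param q Classification tail quantile.
#' @param thresholds Percentile-error thresholds.
#' @param n_boot Bootstrap replicates for decile CIs.
#' @param seed Integer seed.
#' @param offset Log offset `c`.
#' @return A list of class `franklin_evaluation`.
#' @export
evaluate_model <- function(predicted, observed, data = NULL,
                           subgroups = character(), q = 0.20,
                           thresholds = c(20, 40), n_boot = 200L, seed = 1L,
                           offset = 1) {
  fit <- compute_fit_metrics(predicted, observed, offset = offset)
  out <- list(
    fit = fit,
    classification = classify_extremes(predicted, observed, q = q),
    error_frequencies = prediction_error_frequencies(predicted, observed,
                                                     thresholds = thresholds),
    deciles = decile_dispersion(predicted, observed, n_boot = n_boot,
                                seed = seed),
    dispersion = dispersion_decomposition(observed, r2_log = fit$r2_log,
                                          offset = offset),
    subgroups = purrr::map(
      setNames(subgroups, subgroups),
      function(s) subgroup_evaluate(data, predicted, observed, s,
                                    offset = offset)
    )
  )
  structure(out, class = "franklin_evaluation")
}

#' @export
print.franklin_evaluation <- function(x, ...) {
  cat("<franklin_evaluation>\n")
  print(x$fit)
  invisible(x)
}
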