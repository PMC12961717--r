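# Favorable-selection simulation: enrollment log-odds depend linearly on
# the gap between a beneficiary's predicted-cost rank and actual-cost rank;
# overpayment is the mean payment minus mean actual cost among enrollees.

#' Enrollment probability under rank-based favorable selection
#'
#' `p = plogis(qlogis(baseline_rate) + tau * (rank_predicted - rank_actual))`
#' with ranks normalized to [0, 1]. A decile's representative rank is its
#' midpoint (0.05 for the lowest decile, 0.95 for the highest); under this
#' convention a beneficiary in the top predicted decile but bottom actual
#' decile enrolls with probability 52% at `tau = 0.1` and 61% at
#' `tau = 0.5` from a 50% baseline.
#'
#' @param rank_actual,rank_predicted Normalized cohort percentile ranks in
#'   [0, 1] (vectorized).
#' @param tau Selection strength (slope on the enrollment log-odds), >= 0.
#' @param baseline_rate Baseline enrollment probability, strictly inside
#'   (0, 1).
#' @return Enrollment probabilities.
#' @examples
#' enrollment_probability(0.05, 0.95, tau = 0.1)  # ~0.52
#' enrollment_probability(0.05, 0.95, tau = 0.5)  # ~0.61
#' @export
enrollment_probability <- function(rank_actual, rank_predicted, tau,
                                   baseline_rate = 0.5) {
  if (any(rank_actual < 0 | rank_actual > 1) ||
      any(rank_predicted < 0 | rank_predicted > 1)) {
    abort("ranks must lie in [0, 1].")
  }
  check_number(tau, "tau", min = 0)
  check_number(baseline_rate, "baseline_rate")
  if (baseline_rate <= 0 || baseline_rate >= 1) {
    abort("`baseline_rate` must be strictly inside (0, 1).")
  }
  plogis(qlogis(baseline_rate) + tau * (rank_predicted - rank_actual))
}

#' Simulate favorable selection and payer overpayment
#'
#' For each of `n_samples` samples, draws `plan_size` beneficiaries
#' uniformly without replacement from the cohort and enrolls each
#' independently with [enrollment_probability()], using cohort-wide
#' normalized ranks of actual cost and of the payment model's predicted
#' cost. Overpayment per sample is the mean of (payment - actual cost)
#' over enrollees, in USD per member per year. All payment models are
#' evaluated on identical sampled populations with identical enrollment
#' uniforms (common random numbers), so between-model differences are
#' purely model-driven.
#'
#' Payments should be cost-scale predictions calibrated so the cohort-level
#' predictive ratio is 1 (e.g. via [calibrate_deciles()]); at `tau = 0`
#' enrollment is then random and expected overpayment is 0.
#'
#' @param observed_cost Actual annual costs for the full cohort.
#' @param payments A named list of payment vectors (one per model), each
#'   paired with `observed_cost`.
#' @param tau Selection strength.
#' @param baseline_rate Baseline enrollment probability.
#' @param plan_size Beneficiaries drawn per sample (N).
#' @param n_samples Number of simulated samples.
#' @param seed Integer seed.
#' @param conf Confidence level for the percentile interval over samples.
#' @return Tibble of class `franklin_selection` with one row per model:
#'   `model`, `tau`, `overpayment_pmpy`, `ci_lo`, `ci_hi`,
#'   `enrollment_rate`, `plan_size`, `n_samples`; per-sample overpayments
#'   are attached as the `samples` attribute (matrix, sample x model).
#' @export
simulate_selection <- function(observed_cost, payments, tau = 0.3,
                               baseline_rate = 0.5, plan_size = 5000L,
                               n_samples = 500L, seed = 1L, conf = 0.95) {
  if (!is.list(payments) || is.null(names(payments)) ||
      any(names(payments) == "")) {
    abort("`payments` must be a named list of payment vectors.")
  }
  n <- length(observed_cost)
  check_number(plan_size, "plan_size", min = 10, integerish = TRUE)
  check_number(n_samples, "n_samples", min = 1, integerish = TRUE)
  if (plan_size > n) {
    abort(sprintf("cohort (%d) is smaller than plan_size (%d).", n, plan_size))
  }
  for (m in names(payments)) check_paired(payments[[m]], observed_cost)

  rank_actual <- normalized_ranks(observed_cost)
  rank_pred <- lapply(payments, normalized_ranks)
  prob <- lapply(rank_pred, function(rp) {
    enrollment_probability(rank_actual, rp, tau = tau,
                           baseline_rate = baseline_rate)
  })

  models <- names(payments)
  over <- matrix(NA_real_, nrow = n_samples, ncol = length(models),
                 dimnames = list(NULL, models))
  enr_rate <- matrix(NA_real_, nrow = n_samples, ncol = length(models),
                     dimnames = list(NULL, models))
  with_seed(seed, {
    for (s in seq_len(n_samples)) {
      members <- sample.int(n, plan_size)
      u <- runif(plan_size)
      for (m in models) {
        enrolled <- members[u < prob[[m]][members]]
        over[s, m] <- mean(payments[[m]][enrolled] - observed_cost[enrolled])
        enr_rate[s, m] <- length(enrolled) / plan_size
      }
    }
  })

  alpha <- (1 - conf) / 2
  out <- purrr::map_dfr(models, function(m) {
    ci <- quantile(over[, m], c(alpha, 1 - alpha), names = FALSE)
    tibble(
      model = m, tau = tau,
      overpayment_pmpy = mean(over[, m]),
      ci_lo = ci[1], ci_hi = ci[2],
      enrollment_rate = mean(enr_rate[, m]),
      plan_size = plan_size, n_samples = n_samples
    )
  })
  class(out) <- c("franklin_selection", class(out))
  attr(out, "samples") <- over
  out
}

#' Overpayment across a grid of selection strengths
#'
#' Runs [simulate_selection()] at each `tau` with paired seeds and reports
#' a linearity diagnostic (R-squared of mean overpayment against tau, per
#' model).
#'
#' @param observed_cost Actual annual costs.
#' @param payments Named list of payment vectors.
#' @param tau_grid Non-empty vector of selection strengths.
#' @param ... Passed to [simulate_selection()].
#' @return Tibble of class `franklin_overpayment_curve` (one row per tau
#'   per model) with a `linearity` attribute (tibble: model,
#'   r2_linear).
#' @export
overpayment_curve <- function(observed_cost, payments, tau_grid, ...) {
  if (length(tau_grid) == 0) abort("`tau_grid` must be non-empty.")
  res <- purrr::map_dfr(tau_grid, function(tau) {
    simulate_selection(observed_cost, payments, tau = tau, ...)
  })
  lin <- purrr::map_dfr(unique(res$model), function(m) {
    sub <- res[res$model == m, ]
    r2 <- if (nrow(sub) >= 3 && sd(sub$tau) > 0) {
      suppressWarnings(cor(sub$tau, sub$overpayment_pmpy))^2
    } else {
      NA_real_
    }
    tibble(model = m, r2_linear = r2)
  })
  class(res) <- c("franklin_overpayment_curve", class(res))
  attr(res, "linearity") <- lin
  res
}
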