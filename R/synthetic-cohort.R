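# Synthetic claims generator: latent clinical conditions emit co-occurring
# diagnosis codes, and annual cost is log-normal with additive condition and
# demographic effects on the log scale.

#' Configuration for the synthetic claims generator
#'
#' Defines a cohort-generating process with the statistical structure the
#' risk-adjustment pipeline assumes: each beneficiary carries a set of latent
#' clinical conditions; a present condition emits its own block of diagnosis
#' codes (so codes co-occur in structured blocks); annual cost is log-normal,
#' with an additive contribution per condition plus age and sex effects on
#' the natural-log scale.
#'
#' @param n_beneficiaries Number of beneficiaries to generate.
#' @param n_conditions Number of latent clinical conditions (K, at least 2).
#' @param vocab_size Number of distinct synthetic diagnosis codes. Must be at
#'   least `n_conditions * codes_per_condition`; codes beyond the condition
#'   blocks appear only as noise.
#' @param codes_per_condition Codes owned by each condition.
#' @param condition_prevalence Probability each condition is present; scalar
#'   or length-K vector. Default: evenly spaced from 0.25 down to 0.04,
#'   mimicking a mix of common and rarer chronic conditions.
#' @param condition_log_cost_effect Additive log-cost effect per condition;
#'   scalar or length-K vector. Default spans 1.0 down to -0.4 so some
#'   conditions lower expected cost (the model is allowed to learn negative
#'   weights, which an HCC-style nonnegative-weight baseline cannot).
#' @param intercept_log_cost Intercept of the log-cost model (natural log of
#'   USD). Default `log(2000)`: a median annual cost near $2000 with the
#'   default spread puts roughly 20% of beneficiaries below ~$500 and 20%
#'   above ~$7000, the shape of Medicare Part A+B spending.
#' @param age_log_cost_effect Log-cost slope per year of age above 65.
#' @param sex_log_cost_effect Additive log-cost effect for male sex.
#' @param residual_log_sd Residual SD of log cost (sigma, natural-log
#'   scale); zero gives a noiseless cohort.
#' @param code_emission_prob Probability that a present condition emits each
#'   of its codes.
#' @param noise_code_rate Expected count (Poisson) of uniformly random extra
#'   codes per beneficiary.
#' @param zero_dx_fraction Probability a beneficiary's diagnosis set is
#'   emptied (undercoding: latent conditions still drive cost but no codes
#'   are recorded).
#' @param zero_cost_fraction Fraction of beneficiaries whose observed cost is
#'   set to zero, to exercise the downstream log-offset policy.
#' @param female_fraction Probability of female sex.
#' @param age_range Inclusive integer age range to sample from.
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#'
#' @return A validated list of class `franklin_generator_config`.
#' @seealso [generate_cohort()]
#' @export
generator_config <- function(n_beneficiaries = 5000,
                             n_conditions = 10,
                             vocab_size = 400,
                             codes_per_condition = 10,
                             condition_prevalence = NULL,
                             condition_log_cost_effect = NULL,
                             intercept_log_cost = log(2000),
                             age_log_cost_effect = 0.02,
                             sex_log_cost_effect = 0.05,
                             residual_log_sd = 1.0,
                             code_emission_prob = 0.7,
                             noise_code_rate = 1.0,
                             zero_dx_fraction = 0.05,
                             zero_cost_fraction = 0,
                             female_fraction = 0.55,
                             age_range = c(65L, 94L),
                             seed = 1L) {
  check_number(n_beneficiaries, "n_beneficiaries", min = 1, integerish = TRUE)
  check_number(n_conditions, "n_conditions", min = 2, integerish = TRUE)
  check_number(vocab_size, "vocab_size", min = 1, integerish = TRUE)
  check_number(codes_per_condition, "codes_per_condition", min = 1, integerish = TRUE)
  if (n_conditions * codes_per_condition > vocab_size) {
    abort("`vocab_size` must be at least n_conditions * codes_per_condition.")
  }
  K <- as.integer(n_conditions)
  if (is.null(condition_prevalence)) {
    condition_prevalence <- seq(0.25, 0.04, length.out = K)
  }
  condition_prevalence <- rep_len(condition_prevalence, K)
  check_prob(condition_prevalence, "condition_prevalence")
  if (is.null(condition_log_cost_effect)) {
    condition_log_cost_effect <- seq(1.0, -0.4, length.out = K)
  }
  condition_log_cost_effect <- rep_len(condition_log_cost_effect, K)
  if (any(!is.finite(condition_log_cost_effect))) {
    abort("`condition_log_cost_effect` must be finite.")
  }
  check_number(intercept_log_cost, "intercept_log_cost")
  check_number(age_log_cost_effect, "age_log_cost_effect")
  check_number(sex_log_cost_effect, "sex_log_cost_effect")
  check_number(residual_log_sd, "residual_log_sd", min = 0)
  check_prob(code_emission_prob, "code_emission_prob")
  check_number(code_emission_prob, "code_emission_prob", min = 0, max = 1)
  check_number(noise_code_rate, "noise_code_rate", min = 0)
  check_number(zero_dx_fraction, "zero_dx_fraction", min = 0, max = 1)
  check_number(zero_cost_fraction, "zero_cost_fraction", min = 0, max = 1)
  check_number(female_fraction, "female_fraction", min = 0, max = 1)
  if (length(age_range) != 2L || age_range[1] > age_range[2]) {
    abort("`age_range` must be c(min, max) with min <= max.")
  }
  check_number(seed, "seed", integerish = TRUE)

  structure(
    list(
      n_beneficiaries = as.integer(n_beneficiaries),
      n_conditions = K,
      vocab_size = as.integer(vocab_size),
      codes_per_condition = as.integer(codes_per_condition),
      condition_prevalence = condition_prevalence,
      condition_log_cost_effect = condition_log_cost_effect,
      intercept_log_cost = intercept_log_cost,
      age_log_cost_effect = age_log_cost_effect,
      sex_log_cost_effect = sex_log_cost_effect,
      residual_log_sd = residual_log_sd,
      code_emission_prob = code_emission_prob,
      noise_code_rate = noise_code_rate,
      zero_dx_fraction = zero_dx_fraction,
      zero_cost_fraction = zero_cost_fraction,
      female_fraction = female_fraction,
      age_range = as.integer(age_range),
      seed = as.integer(seed)
    ),
    class = "franklin_generator_config"
  )
}

# ICD-10-like synthetic code strings: a letter, two digits, and (for every
# third code) a one-digit subcode, e.g. "A00", "A02" or "C153".
make_code_vocabulary <- function(vocab_size) {
  i <- seq_len(vocab_size) - 1L
  letter <- LETTERS[i %/% 100L + 1L]
  num <- i %% 100L
  base <- sprintf("%s%02d", letter, num)
  sub <- ifelse(i %% 3L == 0L, as.character(i %% 10L), "")
  paste0(base, sub)
}

#' Generate a synthetic claims cohort
#'
#' Draws demographics, latent condition indicators, diagnosis codes and
#' log-normal annual costs according to a [generator_config()]. Cost for
#' beneficiary i is
#' `exp(intercept + age/sex effects + sum of condition effects + N(0, sigma^2))`,
#' rounded to whole cents. A `zero_dx_fraction` stratum keeps its latent
#' conditions (and their cost effects) but records no codes, emulating
#' beneficiaries with no mapped diagnoses.
#'
#' @param config A [generator_config()].
#' @return A list of class `franklin_cohort_sim` with elements:
#'   * `cohort`: tibble with `id`, `age`, `sex` ("F"/"M"), `observed_cost`
#'     (USD) and a neutral `region` subgroup column;
#'   * `diagnoses`: long tibble with `id`, `code` (deduplicated);
#'   * `ground_truth`: list with the latent condition indicator matrix
#'     (`conditions`), the `code` to `condition` assignment table
#'     (`code_conditions`, noise-only codes excluded), the vocabulary, and
#'     `expected_log_cost` (the true linear predictor per beneficiary).
#' @examples
#' sim <- generate_cohort(generator_config(n_beneficiaries = 200, seed = 7))
#' sim$cohort
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "franklin_generator_config")) {
    abort("`config` must be created by generator_config().")
  }
  cfg <- config
  n <- cfg$n_beneficiaries
  K <- cfg$n_conditions

  vocab <- make_code_vocabulary(cfg$vocab_size)
  owned <- matrix(
    vocab[seq_len(K * cfg$codes_per_condition)],
    nrow = K, byrow = TRUE
  )
  code_conditions <- tibble(
    code = as.vector(t(owned)),
    condition = rep(seq_len(K), each = cfg$codes_per_condition)
  )

  with_seed(cfg$seed, {
    ids <- sprintf("B%06d", seq_len(n))
    ages <- sample(seq(cfg$age_range[1], cfg$age_range[2]), n, replace = TRUE,
                   prob = rev(seq_len(cfg$age_range[2] - cfg$age_range[1] + 1L)))
    sex <- ifelse(runif(n) < cfg$female_fraction, "F", "M")
    region <- sample(c("Northeast", "South", "Midwest", "West"), n, replace = TRUE)

    z <- matrix(
      rbinom(n * K, 1L, rep(cfg$condition_prevalence, each = n)),
      nrow = n, ncol = K
    )

    expected_log_cost <- cfg$intercept_log_cost +
      cfg$age_log_cost_effect * (ages - 65) +
      cfg$sex_log_cost_effect * (sex == "M") +
      as.vector(z %*% cfg$condition_log_cost_effect)
    log_cost <- expected_log_cost + rnorm(n, 0, cfg$residual_log_sd)
    cost <- round(exp(log_cost), 2)
    if (cfg$zero_cost_fraction > 0) {
      cost[runif(n) < cfg$zero_cost_fraction] <- 0
    }

    # Condition-emitted codes: each present condition emits each owned code
    # independently with code_emission_prob.
    emit <- which(z == 1L, arr.ind = TRUE)
    dx_list <- vector("list", 3L)
    if (nrow(emit) > 0) {
      rows <- rep(emit[, "row"], each = cfg$codes_per_condition)
      codes <- as.vector(t(owned[emit[, "col"], , drop = FALSE]))
      keep <- runif(length(rows)) < cfg$code_emission_prob
      dx_list[[1L]] <- tibble(id = ids[rows[keep]], code = codes[keep])
    }
    # Uniform noise codes.
    n_noise <- rpois(n, cfg$noise_code_rate)
    if (sum(n_noise) > 0) {
      dx_list[[2L]] <- tibble(
        id = rep(ids, n_noise),
        code = sample(vocab, sum(n_noise), replace = TRUE)
      )
    }
    diagnoses <- dplyr::bind_rows(dx_list)
    if (nrow(diagnoses) == 0) {
      diagnoses <- tibble(id = character(), code = character())
    }
    diagnoses <- dplyr::distinct(diagnoses, .data$id, .data$code)

    if (cfg$zero_dx_fraction > 0) {
      emptied <- ids[runif(n) < cfg$zero_dx_fraction]
      diagnoses <- dplyr::filter(diagnoses, !(.data$id %in% emptied))
    }
    diagnoses <- dplyr::arrange(diagnoses, .data$id, .data$code)

    cohort <- tibble(
      id = ids, age = as.integer(ages), sex = sex,
      observed_cost = cost, region = region
    )
    rownames(z) <- ids

    structure(
      list(
        cohort = cohort,
        diagnoses = diagnoses,
        ground_truth = list(
          conditions = z,
          code_conditions = code_conditions,
          vocabulary = vocab,
          expected_log_cost = setNames(expected_log_cost, ids),
          config = cfg
        )
      ),
      class = "franklin_cohort_sim"
    )
  })
}

#' @export
print.franklin_cohort_sim <- function(x, ...) {
  cfg <- x$ground_truth$config
  cat(sprintf(
    "<franklin_cohort_sim> %d beneficiaries, %d latent conditions, %d codes recorded\n",
    nrow(x$cohort), cfg$n_conditions, nrow(x$diagnoses)
  ))
  invisible(x)
}

#' Summarize a cohort table
#'
#' Demographic and cost summary in long form: counts and shares by sex and
#' 5-year age band, mean and SD of age, cost quantiles, and (when a
#' diagnosis table is supplied) the fraction of beneficiaries with an empty
#' diagnosis set.
#'
#' @param cohort Beneficiary tibble with `id`, `age`, `sex`, `observed_cost`.
#' @param diagnoses Optional long diagnosis tibble (`id`, `code`).
#' @return A tibble with columns `statistic`, `group`, `value`.
#' @export
cohort_summary <- function(cohort, diagnoses = NULL) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    abort("`cohort` must be a non-empty data frame.")
  }
  n <- nrow(cohort)
  sex_tab <- dplyr::count(cohort, .data$sex)
  band <- cut(cohort$age, breaks = seq(65, 100, by = 5), right = FALSE,
              include.lowest = TRUE)
  band_tab <- as.data.frame(table(band))
  qs <- quantile(cohort$observed_cost, c(0.1, 0.25, 0.5, 0.75, 0.9))

  out <- dplyr::bind_rows(
    tibble(statistic = "n", group = "all", value = n),
    tibble(statistic = "sex_count", group = sex_tab$sex, value = as.numeric(sex_tab$n)),
    tibble(statistic = "sex_share", group = sex_tab$sex, value = sex_tab$n / n),
    tibble(statistic = "age_band_count", group = as.character(band_tab$band),
           value = as.numeric(band_tab$Freq)),
    tibble(statistic = "age_mean", group = "all", value = mean(cohort$age)),
    tibble(statistic = "age_sd", group = "all", value = sd(cohort$age)),
    tibble(statistic = "cost_quantile", group = names(qs), value = as.numeric(qs)),
    tibble(statistic = "cost_mean", group = "all", value = mean(cohort$observed_cost))
  )
  if (!is.null(diagnoses)) {
    empty_share <- mean(!(cohort$id %in% unique(diagnoses$id)))
    out <- dplyr::bind_rows(
      out,
      tibble(statistic = "empty_dx_share", group = "all", value = empty_share)
    )
  }
  out
}
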