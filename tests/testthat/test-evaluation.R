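test_that("fit metrics hit their identities and sign cases", {
  obs <- c(10, 200, 3000, 45, 800)
  m <- compute_fit_metrics(obs, obs)
  expect_equal(m$r2_log, 1)
  expect_equal(m$spearman_rho, 1)
  expect_equal(m$ks_log, 0)
  expect_equal(m$mae_cost, 0)

  rev_pred <- sort(obs, decreasing = TRUE)[rank(obs)]
  m2 <- compute_fit_metrics(rev_pred, obs)
  expect_equal(m2$spearman_rho, -1)
  expect_error(compute_fit_metrics(1:4, 1:5), "equal length")
})

test_that("spearman and KS match exhaustive oracles on small vectors", {
  set.seed(71)
  for (trial in 1:25) {
    n <- sample(4:12, 1)
    pred <- sample(1:6, n, replace = TRUE) * 10
    obs <- sample(1:6, n, replace = TRUE) * 10
    m <- compute_fit_metrics(pred, obs)
    if (stats::sd(pred) > 0 && stats::sd(obs) > 0) {
      expect_equal(m$spearman_rho, brute_spearman(pred, obs))
    }
    expect_equal(m$ks_log, brute_ks(log(pred + 1), log(obs + 1)))
  }
})

test_that("extreme-cost classification matches enumeration and edge cases", {
  obs <- c(5, 10, 20, 30, 40, 50, 60, 70, 80, 90)
  perfect <- classify_extremes(obs, obs, q = 0.2)
  expect_true(all(perfect$sensitivity == 1))
  expect_true(all(perfect$specificity == 1))
  expect_true(all(perfect$precision == 1))

  pred <- c(90, 5, 20, 70, 40, 50, 60, 30, 80, 10)
  got <- classify_extremes(pred, obs, q = 0.2, tails = "low")
  m <- 2
  actual_pos <- obs %in% sort(obs)[1:m]
  pred_pos <- pred %in% sort(pred)[1:m]
  tp <- sum(actual_pos & pred_pos)
  expect_equal(got$sensitivity, tp / m)
  expect_equal(got$precision, tp / m)
  expect_equal(got$specificity, sum(!actual_pos & !pred_pos) / (10 - m))
  expect_error(classify_extremes(pred, obs, q = 0.7), "q")
})

test_that("independent predictions recover the chance-level tail overlap", {
  set.seed(73)
  n <- 6000
  obs <- rexp(n)
  pred <- rexp(n)
  got <- classify_extremes(pred, obs, q = 0.2)
  expect_lt(abs(got$sensitivity[1] - 0.2), 0.04)
  expect_lt(abs(got$sensitivity[2] - 0.2), 0.04)
})

test_that("prediction error frequencies follow the percentile-rank contract", {
  obs <- c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100)
  idf <- prediction_error_frequencies(obs, obs)
  expect_true(all(idf$overprediction == 0))
  expect_true(all(idf$underprediction == 0))

  pred <- rev(obs)
  got <- prediction_error_frequencies(pred, obs, thresholds = c(20, 40))
  err <- percentile_ranks(pred) - percentile_ranks(obs)
  expect_equal(got$overprediction, c(mean(err >= 20), mean(err >= 40)))
  expect_equal(got$underprediction, c(mean(err <= -20), mean(err <= -40)))
  # frequencies are nonincreasing in the threshold
  expect_lte(got$overprediction[2], got$overprediction[1])
  expect_lte(got$underprediction[2], got$underprediction[1])

  curve <- prediction_error_frequencies(pred, obs, full_curve = TRUE)
  expect_true(all(diff(curve$overprediction) <= 0))
  expect_true(all(diff(curve$underprediction) <= 0))
})

test_that("decile dispersion matches direct quantile computation", {
  set.seed(79)
  obs <- rep(42, 120)
  pred <- runif(120)
  dd <- decile_dispersion(pred, obs, n_boot = 0)
  expect_true(all(dd$iqr == 0))
  expect_true(all(dd$decile_range == 0))

  obs2 <- exp(rnorm(1000, 7, 1))
  ddi <- decile_dispersion(obs2, obs2, n_boot = 0)
  expect_equal(ddi$predictive_ratio, rep(1, 10))
  dec <- franklinra:::decile_assignment(obs2)
  for (d in c(1, 5, 10)) {
    qs <- quantile(obs2[dec == d], c(0.1, 0.25, 0.75, 0.9), names = FALSE)
    expect_equal(ddi$iqr[d], qs[3] - qs[2])
    expect_equal(ddi$decile_range[d], qs[4] - qs[1])
  }
  ddb <- decile_dispersion(obs2, obs2, n_boot = 50, seed = 1)
  expect_true(all(ddb$iqr_lo <= ddb$iqr & ddb$iqr <= ddb$iqr_hi))
})

test_that("dispersion factors follow their closed forms", {
  d0 <- dispersion_decomposition(sigma = 0, r2_log = 0.3)
  expect_equal(d0$structural_factor, 1)
  expect_equal(d0$residual_factor, 0)

  d1 <- dispersion_decomposition(sigma = 2, r2_log = 1)
  expect_equal(d1$residual_factor, 0)

  d2 <- dispersion_decomposition(sigma = 1, r2_log = 0)
  expect_equal(d2$residual_factor, exp(1) - 1)
  expect_equal(d2$structural_factor, exp(0.5))

  obs <- exp(rnorm(500, 7, 1.1))
  de <- dispersion_decomposition(obs, r2_log = 0.4, offset = 1)
  expect_equal(de$sigma, sd(log(obs + 1)))
})

test_that("plan-level PR variance scales inversely with plan size", {
  simlo <- pr_variance_simulation(sigma = 0.8, r2_log = 0.3, plan_size = 400,
                                  n_plans = 1500, seed = 5)
  simhi <- pr_variance_simulation(sigma = 0.8, r2_log = 0.3, plan_size = 800,
                                  n_plans = 1500, seed = 6)
  expect_equal(simlo$var_pr / simhi$var_pr, 2, tolerance = 0.3)
})

test_that("the downsampled t-test behaves at both extremes", {
  set.seed(83)
  n <- 10000
  obs <- exp(rnorm(n, 7, 1))
  same <- downsampled_ttest(obs, obs, obs, metric = "spearman_rho", seed = 1)
  expect_equal(same$p_value, 1)
  expect_equal(same$mean_difference, 0)

  rand <- sample(obs)
  tt <- downsampled_ttest(obs, rand, obs, metric = "spearman_rho", seed = 2)
  expect_lt(tt$p_value, 0.001)
  expect_gt(tt$mean_difference, 0.9)

  t1 <- downsampled_ttest(obs, rand, obs, metric = "r2_log", seed = 3)
  t2 <- downsampled_ttest(obs, rand, obs, metric = "r2_log", seed = 3)
  expect_identical(t1, t2)
})

test_that("subgroup evaluation splits and flags correctly", {
  set.seed(89)
  n <- 400
  obs <- exp(rnorm(n, 7, 1))
  pred <- obs * exp(rnorm(n, 0, 0.3))
  data <- tibble::tibble(grp = rep("only", n))
  one <- subgroup_evaluate(data, pred, obs, "grp")
  overall <- compute_fit_metrics(pred, obs)
  expect_equal(one$r2_log, overall$r2_log)
  expect_equal(one$share, 1)

  two <- subgroup_evaluate(
    tibble::tibble(grp = rep(c("a", "b"), each = n)),
    c(pred, pred), c(obs, obs), "grp"
  )
  expect_equal(two$mae_cost[1], two$mae_cost[2])

  expect_error(subgroup_evaluate(data, pred, obs, "nope"), "unknown subgroup")

  # a noisier stratum must show larger MAE, matching direct computation
  noisy <- exp(log(obs) + rnorm(n, 0, 1.5))
  dat <- tibble::tibble(grp = rep(c("calm", "noisy"), each = n))
  res <- subgroup_evaluate(dat, c(pred, noisy), c(obs, obs), "grp")
  expect_gt(res$mae_cost[res$level == "noisy"],
            res$mae_cost[res$level == "calm"])
  expect_equal(res$mae_cost[res$level == "noisy"], mean(abs(noisy - obs)))

  small <- subgroup_evaluate(
    tibble::tibble(grp = c(rep("big", 390), rep("tiny", 10))),
    pred, obs, "grp"
  )
  expect_true(small$flagged[small$level == "tiny"])
  expect_false(small$flagged[small$level == "big"])
})

test_that("evaluate_model bundles every section with tidy access", {
  set.seed(97)
  n <- 500
  obs <- exp(rnorm(n, 7, 1))
  pred <- obs * exp(rnorm(n, 0, 0.5))
  ev <- evaluate_model(pred, obs, data = tibble::tibble(g = rep(c("x", "y"), 250)),
                       subgroups = "g", n_boot = 20, seed = 1)
  expect_s3_class(ev, "franklin_evaluation")
  expect_equal(nrow(ev$deciles), 10)
  expect_named(ev$subgroups, "g")
  td <- tidy(ev)
  expect_true(all(c("fit", "classification", "error_frequencies") %in% td$section))
  gl <- glance(ev)
  expect_true(all(c("r2_log", "structural_factor", "residual_factor") %in% names(gl)))
})
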