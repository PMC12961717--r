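test_that("co-occurrence counts enumerate unordered in-vocabulary pairs", {
  dx <- tibble::tibble(id = rep("B1", 3), code = c("A", "B", "C"))
  cooc <- build_cooccurrence(dx, min_count = 1)
  m <- as.matrix(cooc$counts)
  expect_equal(m["A", "B"], 1)
  expect_equal(m["A", "C"], 1)
  expect_equal(m["B", "C"], 1)
  expect_equal(diag(m), c(A = 0, B = 0, C = 0))
  expect_equal(m, t(m))

  singles <- tibble::tibble(id = sprintf("B%d", 1:6),
                            code = rep(c("A", "B", "C"), 2))
  cooc1 <- build_cooccurrence(singles, min_count = 1)
  expect_equal(sum(cooc1$counts), 0)

  expect_error(build_cooccurrence(singles[0, ]), "non-empty")
  expect_error(build_cooccurrence(singles, min_count = 10), "min_count")
})

test_that("within-condition pair counts exceed cross-condition counts", {
  sim <- generate_cohort(generator_config(
    n_beneficiaries = 4000, n_conditions = 3, vocab_size = 60,
    codes_per_condition = 8, noise_code_rate = 0.5, seed = 13
  ))
  cooc <- build_cooccurrence(sim$diagnoses, min_count = 5)
  cc <- sim$ground_truth$code_conditions
  cond_of <- stats::setNames(cc$condition, cc$code)[cooc$vocabulary]
  m <- as.matrix(cooc$counts)
  same <- outer(cond_of, cond_of, "==") & !is.na(outer(cond_of, cond_of, "+"))
  diag(same) <- NA
  within_mean <- mean(m[which(same)])
  cross_mean <- mean(m[which(!same)])
  expect_gt(within_mean, cross_mean)
})

test_that("the PPMI transform matches a hand-computed oracle", {
  counts <- Matrix::Matrix(
    matrix(c(0, 4, 0, 0,
             4, 0, 1, 0,
             0, 1, 0, 3,
             0, 0, 3, 0), 4, 4,
           dimnames = list(LETTERS[1:4], LETTERS[1:4])),
    sparse = TRUE
  )
  p <- franklinra:::ppmi_matrix(counts)
  s <- 16; r <- c(4, 5, 4, 3)
  for (i in 1:4) for (j in 1:4) {
    cij <- as.matrix(counts)[i, j]
    expected <- if (cij > 0) max(0, log(cij * s / (r[i] * r[j]))) else 0
    expect_equal(p[i, j], expected)
  }
})

test_that("exclusively co-occurring codes embed closest to each other", {
  dx <- dplyr::bind_rows(
    tibble::tibble(id = rep(sprintf("P%02d", 1:10), each = 2),
                   code = rep(c("A", "B"), 10)),
    tibble::tibble(id = rep(sprintf("Q%02d", 1:10), each = 2),
                   code = rep(c("C", "D"), 10)),
    tibble::tibble(id = rep(sprintf("R%02d", 1:4), each = 2),
                   code = rep(c("B", "C"), 4))
  )
  cooc <- build_cooccurrence(dx, min_count = 1)
  emb <- suppressWarnings(train_embeddings(cooc, d = 3))
  cosine_sim <- function(a, b) {
    va <- emb$vectors[a, ]; vb <- emb$vectors[b, ]
    sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  }
  expect_gt(cosine_sim("A", "B"), cosine_sim("A", "C"))
  expect_gt(cosine_sim("A", "B"), cosine_sim("A", "D"))
})

test_that("embedding training is deterministic and clips d with a warning", {
  sim <- small_sim(n = 800, seed = 17)
  cooc <- build_cooccurrence(sim$diagnoses, min_count = 3)
  e1 <- train_embeddings(cooc, d = 10)
  e2 <- train_embeddings(cooc, d = 10)
  expect_identical(e1$vectors, e2$vectors)
  expect_warning(train_embeddings(cooc, d = length(cooc$vocabulary) + 5),
                 "clipping")
})

test_that("spherical k-means recovers two well-separated condition blocks", {
  sim <- generate_cohort(generator_config(
    n_beneficiaries = 3000, n_conditions = 2, vocab_size = 24,
    codes_per_condition = 10, code_emission_prob = 0.9,
    noise_code_rate = 0, condition_prevalence = 0.4, seed = 19
  ))
  cooc <- build_cooccurrence(sim$diagnoses, min_count = 5)
  emb <- suppressWarnings(train_embeddings(cooc, d = 8))
  cl <- fit_clusters(emb, k = 2, seed = 3)
  cc <- sim$ground_truth$code_conditions
  truth <- stats::setNames(cc$condition, cc$code)[names(cl$assignment)]
  expect_equal(franklinra:::adjusted_rand_index(cl$assignment, truth), 1)

  # agreement statistic cross-checked against an independent implementation
  expect_equal(
    franklinra:::adjusted_rand_index(cl$assignment, truth),
    mclust::adjustedRandIndex(cl$assignment, truth)
  )
})

test_that("k = vocabulary gives singleton clusters with zero inertia", {
  set.seed(23)
  vecs <- matrix(rnorm(12 * 4), 12, 4,
                 dimnames = list(sprintf("C%02d", 1:12), NULL))
  emb <- manual_embeddings(vecs)
  cl <- suppressWarnings(fit_clusters(emb, k = 20, seed = 1))
  expect_equal(cl$k, 12)
  expect_equal(cl$inertia, 0, tolerance = 1e-8)
  expect_equal(length(unique(cl$assignment)), 12)

  c1 <- fit_clusters(emb, k = 4, seed = 9)
  c2 <- fit_clusters(emb, k = 4, seed = 9)
  expect_identical(c1$centers, c2$centers)
  expect_error(fit_clusters(emb, k = 1), "k")
})

test_that("embedding inner products reconstruct the PPMI kernel's PSD part", {
  sim <- small_sim(n = 500, seed = 59)
  cooc <- build_cooccurrence(sim$diagnoses, min_count = 4)
  v <- length(cooc$vocabulary)
  emb <- suppressWarnings(train_embeddings(cooc, d = v - 1, alpha = 0.5))
  ppmi <- franklinra:::ppmi_matrix(cooc$counts)
  eig <- eigen(ppmi, symmetric = TRUE)
  psd_part <- eig$vectors %*% diag(pmax(eig$values, 0)) %*% t(eig$vectors)
  recon <- emb$vectors %*% t(emb$vectors)
  # full-rank limit: at most one positive direction can be dropped by d=v-1
  expect_lt(max(abs(recon - psd_part)), max(eig$values) * 0.05 + 1e-8)
})

test_that("cluster features are max cosine similarities", {
  vecs <- rbind(A = c(1, 0), B = c(0, 1), C = c(1, 1) / sqrt(2))
  centers <- rbind(c(1, 0), c(0, 1))
  emb <- manual_embeddings(vecs)
  cl <- manual_clusters(centers, rownames(vecs))
  cohort <- tibble::tibble(id = c("B1", "B2", "B3"), age = 70L, sex = "F",
                           observed_cost = 1)
  dx <- tibble::tibble(id = c("B1", "B2", "B2", "B3"),
                       code = c("A", "B", "C", "OOV"))
  f <- compute_cluster_features(cohort, dx, emb, cl)
  # B1 holds only A (= center 1): feature 1 is exactly 1
  expect_equal(f$cluster_001[1], 1)
  expect_equal(f$cluster_002[1], 0)
  # B2 holds B and C: hand-computed max cosines
  expect_equal(f$cluster_001[2], max(0, 1 / sqrt(2)))
  expect_equal(f$cluster_002[2], max(1, 1 / sqrt(2)))
  # B3 has only an out-of-vocabulary code: zero vector
  expect_equal(unlist(f[3, -1], use.names = FALSE), c(0, 0))
  expect_true(all(as.matrix(f[, -1]) >= -1 & as.matrix(f[, -1]) <= 1))
})

test_that("adding a code never decreases any feature entry", {
  sim <- small_sim(n = 700, seed = 29)
  cooc <- build_cooccurrence(sim$diagnoses, min_count = 3)
  emb <- suppressWarnings(train_embeddings(cooc, d = 8))
  cl <- fit_clusters(emb, k = 4, seed = 2)
  cohort1 <- tibble::tibble(id = "Z1", age = 70L, sex = "F", observed_cost = 1)
  codes <- cooc$vocabulary[1:5]
  f_small <- compute_cluster_features(
    cohort1, tibble::tibble(id = "Z1", code = codes[1:2]), emb, cl)
  f_big <- compute_cluster_features(
    cohort1, tibble::tibble(id = "Z1", code = codes), emb, cl)
  expect_true(all(as.matrix(f_big[, -1]) >= as.matrix(f_small[, -1]) - 1e-12))
})

test_that("bootstrap cluster partitions are stable on blocked data", {
  sim <- generate_cohort(generator_config(
    n_beneficiaries = 1500, n_conditions = 3, vocab_size = 30,
    codes_per_condition = 10, code_emission_prob = 0.9, noise_code_rate = 0,
    condition_prevalence = 0.4, seed = 37
  ))
  st_fixed <- cluster_stability(sim$diagnoses, n_boot = 2, d = 6, k = 3,
                                min_count = 5, seed = 1, resample = FALSE)
  expect_equal(st_fixed$mean_agreement, 1)

  st <- cluster_stability(sim$diagnoses, n_boot = 3, d = 6, k = 3,
                          min_count = 5, seed = 1)
  expect_gte(st$mean_agreement, 0.95)

  noise <- generate_cohort(generator_config(
    n_beneficiaries = 1500, n_conditions = 2, vocab_size = 30,
    codes_per_condition = 1, condition_prevalence = 0,
    noise_code_rate = 6, seed = 41
  ))
  st_noise <- cluster_stability(noise$diagnoses, n_boot = 3, d = 6, k = 3,
                                min_count = 5, seed = 1)
  expect_lt(st_noise$mean_agreement, st$mean_agreement)
})
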