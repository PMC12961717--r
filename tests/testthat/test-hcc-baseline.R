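test_that("the bundled toy map loads and a 115-category map is accepted", {
  dir <- system.file("extdata", "toy_hcc_map", package = "franklinra")
  map <- load_category_map(dir, base_cost = 12963)
  expect_s3_class(map, "franklin_category_map")
  expect_equal(nrow(map$categories), 10)

  big <- category_map(
    categories = tibble::tibble(category = sprintf("HCC%03d", 1:115),
                                weight = seq(0.1, 2, length.out = 115)),
    mappings = tibble::tibble(code = "A00", category = "HCC001"),
    cells = tibble::tibble(age_min = 65, age_max = 130, sex = c("F", "M"),
                           weight = 0.4)
  )
  expect_equal(length(big$categories$weight), 115)
})

test_that("an empty mapping file yields demographic-only scores", {
  dir <- withr::local_tempdir()
  file.copy(list.files(system.file("extdata", "toy_hcc_map", package = "franklinra"),
                       full.names = TRUE), dir)
  writeLines("code,category", file.path(dir, "mappings.csv"))
  map <- load_category_map(dir, base_cost = 1000)
  cohort <- tibble::tibble(id = c("B1", "B2"), age = c(67L, 82L),
                           sex = c("F", "M"), observed_cost = c(1, 1))
  dx <- tibble::tibble(id = "B1", code = "E11")
  sc <- hcc_score(cohort, dx, map)
  expect_equal(sc$score, c(0.35, 0.60))
  expect_equal(sc$n_categories, c(0L, 0L))
})

test_that("map validation catches cycles and negative weights", {
  cats <- tibble::tibble(category = c("A", "B"), weight = c(0.1, 0.2))
  maps <- tibble::tibble(code = "X1", category = "A")
  cells <- tibble::tibble(age_min = 65, age_max = 130, sex = "F", weight = 0.1)
  expect_error(
    category_map(cats, maps, cells,
                 hierarchy = tibble::tibble(dominant = c("A", "B"),
                                            subordinate = c("B", "A"))),
    "cycle"
  )
  expect_error(
    category_map(dplyr::mutate(cats, weight = c(-0.1, 0.2)), maps, cells),
    ">= 0"
  )
})

test_that("hierarchy suppression is transitive, idempotent and as figured", {
  map <- tiny_map()
  # severe + mild present -> severe only
  expect_equal(assign_categories(c("A01", "A02"), map), "C_severe")
  expect_equal(assign_categories(character(0), map), character(0))
  # three codes mapping into one category -> singleton
  expect_equal(assign_categories(c("A02", "B01", "B01"), map), "C_mild")

  # transitive chain A -> B -> C: A present suppresses both B and C
  chain <- category_map(
    categories = tibble::tibble(category = c("A", "B", "C"),
                                weight = c(0.3, 0.2, 0.1)),
    mappings = tibble::tibble(code = c("X1", "X2", "X3"),
                              category = c("A", "B", "C")),
    cells = tibble::tibble(age_min = 65, age_max = 130, sex = c("F", "M"),
                           weight = 0),
    hierarchy = tibble::tibble(dominant = c("A", "B"), subordinate = c("B", "C"))
  )
  expect_equal(assign_categories(c("X1", "X2", "X3"), chain), "A")

  # idempotence: re-assigning the surviving categories' codes is stable
  surv <- assign_categories(c("A01", "A02", "B02"), map)
  codes_back <- map$mappings$code[map$mappings$category %in% surv]
  expect_equal(assign_categories(codes_back, map), surv)
})

test_that("scoring arithmetic matches hand computation", {
  map <- tiny_map(base_cost = 12963)
  cohort <- tibble::tibble(id = "B1", age = 70L, sex = "F", observed_cost = 1)
  # no mapped codes, cell weight 0.4 -> predicted cost 0.4 * 12963
  sc <- hcc_score(cohort, tibble::tibble(id = character(), code = character()), map)
  expect_equal(sc$predicted_cost, 5185.20)

  # cell 0.4 + C_severe 0.5 + C_other 0.3 (C_mild suppressed) = 1.2
  sc2 <- hcc_score(cohort, tibble::tibble(id = "B1", code = c("A01", "A02", "B02")), map)
  expect_equal(sc2$score, 1.2)

  expect_error(
    hcc_score(tibble::tibble(id = "B1", age = 40L, sex = "F", observed_cost = 1),
              tibble::tibble(id = character(), code = character()),
              tiny_map()),
    "age=40"
  )
})

test_that("adding a mapped, non-suppressed code never decreases the score", {
  map <- tiny_map()
  cohort <- tibble::tibble(id = "B1", age = 70L, sex = "M", observed_cost = 1)
  base_codes <- c("B01")
  s0 <- hcc_score(cohort, tibble::tibble(id = "B1", code = base_codes), map)$score
  for (extra in c("A01", "B02", "ZZZ")) {
    s1 <- hcc_score(cohort,
                    tibble::tibble(id = "B1", code = c(base_codes, extra)),
                    map)$score
    expect_gte(s1, s0)
  }
})

test_that("with no hierarchy the score is the plain weighted sum (oracle)", {
  set.seed(31)
  for (trial in 1:20) {
    k <- sample(3:8, 1)
    cats <- tibble::tibble(category = sprintf("C%02d", 1:k),
                           weight = round(runif(k), 3))
    codes <- sprintf("X%02d", 1:(2 * k))
    maps <- tibble::tibble(code = codes,
                           category = sample(cats$category, 2 * k, replace = TRUE))
    map <- category_map(cats, maps,
                        cells = tibble::tibble(age_min = 65, age_max = 130,
                                               sex = c("F", "M"), weight = 0.25))
    dx_codes <- sample(codes, sample(0:(2 * k), 1))
    present <- unique(maps$category[maps$code %in% dx_codes])
    oracle <- 0.25 + sum(cats$weight[cats$category %in% present])
    sc <- hcc_score(
      tibble::tibble(id = "B1", age = 70L, sex = "F", observed_cost = 1),
      tibble::tibble(id = rep("B1", length(dx_codes)), code = dx_codes),
      map
    )
    expect_equal(sc$score, oracle)
  }
})

test_that("normalize_scores rescales to mean one", {
  expect_equal(normalize_scores(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(normalize_scores(c(1, 3)), c(0.5, 1.5))
  set.seed(5)
  s <- rexp(200)
  expect_equal(mean(normalize_scores(s)), 1, tolerance = 1e-12)
  expect_error(normalize_scores(c(0, 0)), "mean score is 0")
})

test_that("disease-interaction weights add when both categories survive", {
  map <- category_map(
    categories = tibble::tibble(category = c("A", "B"), weight = c(0.3, 0.2)),
    mappings = tibble::tibble(code = c("X1", "X2"), category = c("A", "B")),
    cells = tibble::tibble(age_min = 65, age_max = 130, sex = c("F", "M"),
                           weight = 0.1),
    interactions = tibble::tibble(category_a = "A", category_b = "B",
                                  weight = 0.15)
  )
  cohort <- tibble::tibble(id = "B1", age = 70L, sex = "F", observed_cost = 1)
  sc <- hcc_score(cohort, tibble::tibble(id = "B1", code = c("X1", "X2")), map)
  expect_equal(sc$score, 0.1 + 0.3 + 0.2 + 0.15)
})
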