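# Structurally faithful HCC-style scorer: diagnosis codes map into disease
# categories, a severity hierarchy suppresses subordinate categories, and
# the risk score is a demographic cell weight plus a nonnegative-weighted
# category sum, converted to dollars by a base cost.

#' Construct an HCC-style category map
#'
#' @param categories Tibble with `category` (id) and `weight` (nonnegative).
#' @param mappings Tibble with `code`, `category`: the partial ICD-to-category
#'   assignment (codes without a row are simply not scored).
#' @param cells Tibble with `age_min`, `age_max`, `sex`, `weight`: demographic
#'   cell weights. Cells are matched by `age_min <= age <= age_max` and sex.
#' @param hierarchy Optional tibble with `dominant`, `subordinate` directed
#'   edges; a present dominant category suppresses its (transitively)
#'   subordinate categories. Must be acyclic.
#' @param base_cost Dollars per unit risk score (CMS published $12,963 for
#'   2024).
#' @param interactions Optional tibble with `category_a`, `category_b`,
#'   `weight`: extra weight added when both categories survive suppression.
#' @return A list of class `franklin_category_map`.
#' @export
category_map <- function(categories, mappings, cells, hierarchy = NULL,
                         base_cost = 12963, interactions = NULL) {
  for (col in c("category", "weight")) {
    if (!col %in% names(categories)) abort(sprintf("`categories` needs column `%s`.", col))
  }
  if (any(categories$weight < 0)) abort("category weights must be >= 0.")
  if (anyDuplicated(categories$category)) abort("category ids must be unique.")
  for (col in c("code", "category")) {
    if (!col %in% names(mappings)) abort(sprintf("`mappings` needs column `%s`.", col))
  }
  unknown_cat <- setdiff(mappings$category, categories$category)
  if (length(unknown_cat) > 0) {
    abort(sprintf("mappings reference unknown categories: %s",
                  paste(unique(unknown_cat), collapse = ", ")))
  }
  for (col in c("age_min", "age_max", "sex", "weight")) {
    if (!col %in% names(cells)) abort(sprintf("`cells` needs column `%s`.", col))
  }
  if (any(cells$weight < 0)) abort("demographic cell weights must be >= 0.")
  check_number(base_cost, "base_cost", min = 0)

  if (is.null(hierarchy) || nrow(hierarchy) == 0) {
    hierarchy <- tibble(dominant = character(), subordinate = character())
  }
  bad_end <- setdiff(c(hierarchy$dominant, hierarchy$subordinate),
                     categories$category)
  if (length(bad_end) > 0) {
    abort(sprintf("hierarchy references unknown categories: %s",
                  paste(unique(bad_end), collapse = ", ")))
  }
  cyc <- find_cycle(hierarchy$dominant, hierarchy$subordinate)
  if (!is.null(cyc)) {
    abort(sprintf("hierarchy contains a cycle: %s", paste(cyc, collapse = " -> ")))
  }
  if (!is.null(interactions)) {
    for (col in c("category_a", "category_b", "weight")) {
      if (!col %in% names(interactions)) {
        abort(sprintf("`interactions` needs column `%s`.", col))
      }
    }
    if (any(interactions$weight < 0)) abort("interaction weights must be >= 0.")
  }

  structure(
    list(
      categories = as_tibble(categories),
      mappings = dplyr::distinct(as_tibble(mappings), .data$code, .data$category),
      cells = as_tibble(cells),
      hierarchy = as_tibble(hierarchy),
      base_cost = base_cost,
      interactions = if (is.null(interactions)) NULL else as_tibble(interactions),
      # subordinate -> all (transitive) dominant ancestors, precomputed
      ancestors = transitive_ancestors(hierarchy$dominant, hierarchy$subordinate)
    ),
    class = "franklin_category_map"
  )
}

# Depth-first cycle search on directed edges; returns a cycle path or NULL.
find_cycle <- function(from, to) {
  nodes <- unique(c(from, to))
  adj <- split(to, factor(from, levels = nodes))
  state <- setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 active, 2 done
  path <- character(0)
  result <- NULL
  visit <- function(v) {
    if (!is.null(result)) return()
    if (state[[v]] == 1L) {
      result <<- c(path[which(path == v)[1]:length(path)], v)
      return()
    }
    if (state[[v]] == 2L) return()
    state[[v]] <<- 1L
    path <<- c(path, v)
    for (w in adj[[v]]) visit(w)
    path <<- path[-length(path)]
    state[[v]] <<- 2L
  }
  for (v in nodes) visit(v)
  result
}

# For each node, the set of categories that dominate it via any directed path.
transitive_ancestors <- function(from, to) {
  nodes <- unique(c(from, to))
  parents <- split(from, factor(to, levels = nodes))
  anc <- list()
  get_anc <- function(v) {
    if (!is.null(anc[[v]])) return(anc[[v]])
    p <- parents[[v]]
    res <- unique(c(p, unlist(lapply(p, get_anc))))
    anc[[v]] <<- res
    res
  }
  for (v in nodes) get_anc(v)
  anc
}

#' Load a category map from a directory of CSV tables
#'
#' Expects `categories.csv` (category, weight), `mappings.csv` (code,
#' category), `cells.csv` (age_min, age_max, sex, weight) and optionally
#' `hierarchy.csv` (dominant, subordinate) and `interactions.csv`
#' (category_a, category_b, weight) in `dir`.
#'
#' @param dir Directory containing the CSV tables.
#' @param base_cost Dollars per unit score.
#' @return A `franklin_category_map`.
#' @export
load_category_map <- function(dir, base_cost = 12963) {
  rd <- function(f) readr::read_csv(file.path(dir, f), show_col_types = FALSE,
                                    progress = FALSE)
  hier_path <- file.path(dir, "hierarchy.csv")
  inter_path <- file.path(dir, "interactions.csv")
  mappings <- rd("mappings.csv")
  if (nrow(mappings) == 0) {
    mappings <- tibble(code = character(), category = character())
  }
  category_map(
    categories = rd("categories.csv"),
    mappings = mappings,
    cells = rd("cells.csv"),
    hierarchy = if (file.exists(hier_path)) rd("hierarchy.csv") else NULL,
    base_cost = base_cost,
    interactions = if (file.exists(inter_path)) rd("interactions.csv") else NULL
  )
}

#' Assign (and hierarchically suppress) categories for a diagnosis set
#'
#' Maps each code through the ICD-to-category assignment, silently ignoring
#' unmapped codes, then removes every category with a dominant ancestor also
#' present (suppression is transitive along hierarchy edges).
#'
#' @param dx_codes Character vector of diagnosis codes.
#' @param map A `franklin_category_map`.
#' @return Character vector of surviving category ids (sorted).
#' @export
assign_categories <- function(dx_codes, map) {
  stopifnot(inherits(map, "franklin_category_map"))
  cats <- unique(map$mappings$category[map$mappings$code %in% dx_codes])
  if (length(cats) <= 1L) return(sort(cats))
  suppressed <- vapply(cats, function(cc) {
    anc <- map$ancestors[[cc]]
    !is.null(anc) && any(anc %in% cats)
  }, logical(1))
  sort(cats[!suppressed])
}

#' Score beneficiaries with the HCC-style model
#'
#' Each beneficiary's risk score is their demographic cell weight plus the
#' weights of their surviving categories (plus any interaction weights);
#' predicted cost is score times the base cost.
#'
#' @param cohort Beneficiary tibble (`id`, `age`, `sex`, ...).
#' @param diagnoses Long diagnosis tibble (`id`, `code`).
#' @param map A `franklin_category_map`.
#' @return Tibble with `id`, `n_categories`, `score`, `predicted_cost`.
#' @export
hcc_score <- function(cohort, diagnoses, map) {
  stopifnot(inherits(map, "franklin_category_map"))
  cell_w <- demographic_weights(cohort, map)
  cat_w <- setNames(map$categories$weight, map$categories$category)

  dx_by_id <- split(diagnoses$code, diagnoses$id)
  cats_by_ben <- lapply(cohort$id, function(b) {
    codes <- dx_by_id[[b]]
    if (is.null(codes)) character(0) else assign_categories(codes, map)
  })
  score_dx <- vapply(cats_by_ben, function(cats) {
    s <- sum(cat_w[cats])
    if (!is.null(map$interactions) && length(cats) > 1) {
      hit <- map$interactions$category_a %in% cats &
        map$interactions$category_b %in% cats
      s <- s + sum(map$interactions$weight[hit])
    }
    s
  }, numeric(1))
  n_cat <- lengths(cats_by_ben)

  score <- cell_w + score_dx
  tibble(
    id = cohort$id,
    n_categories = n_cat,
    score = score,
    predicted_cost = score * map$base_cost
  )
}

demographic_weights <- function(cohort, map) {
  cells <- map$cells
  w <- rep(NA_real_, nrow(cohort))
  for (i in seq_len(nrow(cells))) {
    hit <- cohort$age >= cells$age_min[i] & cohort$age <= cells$age_max[i] &
      cohort$sex == cells$sex[i]
    w[hit & is.na(w)] <- cells$weight[i]
  }
  if (anyNA(w)) {
    j <- which(is.na(w))[1]
    abort(sprintf(
      "no demographic cell covers (age=%s, sex=%s).",
      cohort$age[j], cohort$sex[j]
    ))
  }
  w
}

#' Scale risk scores so the cohort mean is 1
#'
#' @param scores Numeric vector of risk scores.
#' @return Scores divided by their mean (mean of the result is 1).
#' @export
normalize_scores <- function(scores) {
  if (length(scores) == 0) abort("`scores` must be non-empty.")
  m <- mean(scores)
  if (m == 0) abort("cannot normalize: mean score is 0.")
  scores / m
}
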