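# Reading, writing and splitting beneficiary-level claims extracts.
# On-disk format: two UTF-8 CSVs with header rows — a beneficiary table
# (id, age, sex, observed_cost, optional subgroup columns) and a long
# diagnosis table (id, code). Costs are written with 2 fractional digits.

#' Read a cohort from beneficiary and diagnosis CSV tables
#'
#' Joins the long diagnosis table onto the beneficiary table. Beneficiaries
#' absent from the diagnosis table get an empty diagnosis set; duplicate
#' `(id, code)` pairs collapse to one.
#'
#' @param beneficiary_file CSV with columns `id`, `age`, `sex`,
#'   `observed_cost` and any number of extra subgroup columns.
#' @param diagnosis_file CSV with columns `id`, `code`.
#' @return A list with `cohort` (tibble, one row per beneficiary) and
#'   `diagnoses` (deduplicated long tibble).
#' @export
read_cohort <- function(beneficiary_file, diagnosis_file) {
  cohort <- readr::read_csv(
    beneficiary_file, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(id = "c", sex = "c")  # "F" must not parse as FALSE
  )
  required <- c("id", "age", "sex", "observed_cost")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    abort(sprintf("beneficiary table is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  cohort$id <- as.character(cohort$id)
  if (anyDuplicated(cohort$id)) {
    abort("beneficiary ids must be unique.")
  }
  if (any(cohort$observed_cost < 0)) {
    abort("observed_cost must be >= 0 for every beneficiary.")
  }
  if (!all(cohort$sex %in% c("F", "M"))) {
    abort('`sex` must be coded "F" or "M".')
  }

  diagnoses <- readr::read_csv(
    diagnosis_file, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = "c")
  )
  if (nrow(diagnoses) == 0 && ncol(diagnoses) == 0) {
    diagnoses <- tibble(id = character(), code = character())
  }
  missing_dx <- setdiff(c("id", "code"), names(diagnoses))
  if (length(missing_dx) > 0) {
    abort(sprintf("diagnosis table is missing required column(s): %s",
                  paste(missing_dx, collapse = ", ")))
  }
  diagnoses$id <- as.character(diagnoses$id)
  diagnoses$code <- as.character(diagnoses$code)
  unknown <- setdiff(unique(diagnoses$id), cohort$id)
  if (length(unknown) > 0) {
    abort(sprintf(
      "diagnosis table references %d unknown beneficiary id(s): %s",
      length(unknown), paste(head(unknown, 10), collapse = ", ")
    ))
  }
  diagnoses <- dplyr::distinct(diagnoses, .data$id, .data$code)
  diagnoses <- dplyr::arrange(diagnoses, .data$id, .data$code)

  list(cohort = as_tibble(cohort), diagnoses = diagnoses)
}

#' Write a cohort to beneficiary and diagnosis CSV tables
#'
#' Inverse of [read_cohort()]. Costs are written as decimal USD with two
#' fractional digits, so a write/read round trip of cent-valued costs is
#' exact.
#'
#' @param cohort Beneficiary tibble.
#' @param diagnoses Long diagnosis tibble.
#' @param beneficiary_file,diagnosis_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, diagnoses, beneficiary_file, diagnosis_file) {
  out <- cohort
  out$observed_cost <- sprintf("%.2f", cohort$observed_cost)
  readr::write_csv(out, beneficiary_file, progress = FALSE)
  readr::write_csv(diagnoses, diagnosis_file, progress = FALSE)
  invisible(c(beneficiary_file, diagnosis_file))
}

#' Randomly split a cohort into embeddings/training/validation/test
#'
#' Labels each beneficiary with exactly one split. The allocation is a
#' seeded permutation followed by contiguous blocks sized by
#' largest-remainder rounding, so realized counts are within one of the
#' exact proportions and identical seeds give identical splits.
#'
#' @param cohort Beneficiary tibble.
#' @param fractions Four probabilities (embeddings, training, validation,
#'   test) summing to 1. Default `c(0.2, 0.4, 0.2, 0.2)`.
#' @param seed Integer seed.
#' @return The cohort tibble with a `split` factor column.
#' @export
split_cohort <- function(cohort,
                         fractions = c(embeddings = 0.2, training = 0.4,
                                       validation = 0.2, test = 0.2),
                         seed = 1L) {
  if (length(fractions) != 4L) abort("`fractions` must have length 4.")
  if (abs(sum(fractions) - 1) > 1e-9) {
    abort(sprintf("`fractions` must sum to 1 (got %.12f).", sum(fractions)))
  }
  check_prob(fractions, "fractions")
  labels <- c("embeddings", "training", "validation", "test")
  n <- nrow(cohort)

  # Largest-remainder rounding of n * fractions to integer block sizes.
  exact <- n * fractions
  sizes <- floor(exact)
  remainder <- n - sum(sizes)
  if (remainder > 0) {
    extra <- order(exact - sizes, decreasing = TRUE)[seq_len(remainder)]
    sizes[extra] <- sizes[extra] + 1L
  }

  perm <- with_seed(seed, sample.int(n))
  split <- character(n)
  split[perm] <- rep(labels, times = sizes)
  cohort$split <- factor(split, levels = labels)
  cohort
}
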