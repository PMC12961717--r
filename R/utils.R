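# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package functions never disturb the global stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

check_number <- function(x, name, min = -Inf, max = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, min, max, x))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort(sprintf("`%s` must be a whole number, got %s.", name, x))
  }
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be probabilities in [0, 1].", name))
  }
  invisible(x)
}

check_paired <- function(predicted, observed, min_length = 1L) {
  if (length(predicted) != length(observed)) {
    abort(sprintf(
      "`predicted` (%d) and `observed` (%d) must have equal length.",
      length(predicted), length(observed)
    ))
  }
  if (length(predicted) < min_length) {
    abort(sprintf("need at least %d paired values.", min_length))
  }
  if (any(!is.finite(predicted)) || any(!is.finite(observed))) {
    abort("`predicted` and `observed` must be finite.")
  }
  invisible(NULL)
}

#' Percentile ranks on a 0-100 scale
#'
#' Average-rank tie handling, scaled so that ranks lie in (0, 100]. Used for
#' the substantial-prediction-error frequencies and the selection simulator.
#'
#' @param x Numeric vector.
#' @return Numeric vector of percentile ranks in (0, 100].
#' @export
percentile_ranks <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  rank(x, ties.method = "average") / length(x) * 100
}

# Normalized ranks in (0, 1): (rank - 0.5) / n. Under this convention a
# decile's representative member sits at the decile midpoint (0.05 for the
# lowest decile, 0.95 for the highest).
normalized_ranks <- function(x) {
  n <- length(x)
  (rank(x, ties.method = "average") - 0.5) / n
}

# Equal-count decile assignment by `x`, ties broken stably by original order.
decile_assignment <- function(x, n_groups = 10L) {
  n <- length(x)
  ord <- order(x, seq_along(x))
  sizes <- rep(n %/% n_groups, n_groups)
  extra <- n %% n_groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  grp <- integer(n)
  grp[ord] <- rep(seq_len(n_groups), times = sizes)
  grp
}

# Two-sample Kolmogorov-Smirnov statistic: sup over the pooled sample of the
# absolute ECDF difference. Written directly (rather than via ks.test) so the
# statistic is available without the test machinery; tie-safe and O(n log n).
ks_statistic <- function(x, y) {
  x <- sort(x)
  y <- sort(y)
  pts <- c(x, y)
  # findInterval on a sorted vector counts elements <= each evaluation point,
  # which is exactly n * ECDF(point), ties included.
  fx <- findInterval(pts, x) / length(x)
  fy <- findInterval(pts, y) / length(y)
  max(abs(fx - fy))
}

# Adjusted Rand index between two labelings of the same items.
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("labelings must have equal length.")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

cosine_normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}
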