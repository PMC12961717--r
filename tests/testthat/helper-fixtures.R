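# Shared fixtures, built in code at test time.

small_sim <- function(n = 2000, K = 5, seed = 11, ...) {
  generate_cohort(generator_config(
    n_beneficiaries = n, n_conditions = K, vocab_size = 120,
    codes_per_condition = 8, seed = seed, ...
  ))
}

# A tiny hand-written category map: three categories, one suppression edge.
tiny_map <- function(base_cost = 1000, hierarchy = TRUE) {
  category_map(
    categories = tibble::tibble(
      category = c("C_severe", "C_mild", "C_other"),
      weight = c(0.5, 0.2, 0.3)
    ),
    mappings = tibble::tibble(
      code = c("A01", "A02", "B01", "B02"),
      category = c("C_severe", "C_mild", "C_mild", "C_other")
    ),
    cells = tibble::tibble(
      age_min = c(65, 65), age_max = c(130, 130),
      sex = c("F", "M"), weight = c(0.4, 0.45)
    ),
    hierarchy = if (hierarchy) {
      tibble::tibble(dominant = "C_severe", subordinate = "C_mild")
    } else {
      NULL
    },
    base_cost = base_cost
  )
}

# Hand-constructed embedding/cluster objects for feature tests.
manual_embeddings <- function(vectors) {
  structure(
    list(vectors = vectors, d = ncol(vectors), alpha = 0.5,
         singular_values = rep(1, ncol(vectors)),
         meta = list(method = "manual")),
    class = "franklin_embeddings"
  )
}

manual_clusters <- function(centers, vocabulary) {
  structure(
    list(centers = centers,
         assignment = stats::setNames(rep(1L, length(vocabulary)), vocabulary),
         inertia = 0, k = nrow(centers), seed = 0L),
    class = "franklin_clusters"
  )
}

# Brute-force oracles (deliberately naive; used on inputs of size <= 12).

brute_ranks <- function(x) {
  vapply(seq_along(x), function(i) {
    less <- sum(x < x[i])
    ties <- sum(x == x[i])
    less + (1 + ties) / 2
  }, numeric(1))
}

brute_spearman <- function(x, y) {
  rx <- brute_ranks(x); ry <- brute_ranks(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

brute_ks <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(p) abs(mean(x <= p) - mean(y <= p)), numeric(1)))
}

# Transitive suppression by explicit reachability (repeated edge expansion).
brute_suppress <- function(present, edges) {
  nodes <- unique(c(edges$dominant, edges$subordinate, present))
  reach <- matrix(FALSE, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    reach[edges$dominant[i], edges$subordinate[i]] <- TRUE
  }
  for (k in nodes) for (i in nodes) for (j in nodes) {
    if (reach[i, k] && reach[k, j]) reach[i, j] <- TRUE
  }
  keep <- vapply(present, function(cc) {
    !any(reach[setdiff(present, cc), cc])
  }, logical(1))
  sort(present[keep])
}
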