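# Diagnosis-code embeddings from within-profile co-occurrence (PPMI +
# truncated SVD), spherical k-means clusters over the embedding space, and
# per-beneficiary maximum-similarity cluster features.

#' Build the code co-occurrence matrix from diagnosis profiles
#'
#' Treats each beneficiary's diagnosis set as an unordered profile: every
#' unordered pair of distinct in-vocabulary codes within a profile
#' increments its count by one. The vocabulary is restricted to codes
#' appearing in at least `min_count` profiles.
#'
#' @param diagnoses Long diagnosis tibble (`id`, `code`), typically
#'   restricted to the embeddings split.
#' @param min_count Minimum number of profiles a code must appear in to
#'   enter the vocabulary (rarer codes yield degenerate embeddings).
#' @return A list of class `franklin_cooccurrence` with `vocabulary`,
#'   `counts` (symmetric sparse matrix, zero diagonal), `profile_counts`
#'   (per-code number of profiles) and `n_profiles`.
#' @export
build_cooccurrence <- function(diagnoses, min_count = 5L) {
  if (!is.data.frame(diagnoses) || nrow(diagnoses) == 0) {
    abort("`diagnoses` must be a non-empty data frame (empty embeddings split?).")
  }
  check_number(min_count, "min_count", min = 1, integerish = TRUE)
  dx <- dplyr::distinct(as_tibble(diagnoses), .data$id, .data$code)
  freq <- table(dx$code)
  vocab <- sort(names(freq)[freq >= min_count])
  if (length(vocab) == 0) {
    abort("no code reaches `min_count`; vocabulary is empty.")
  }
  dx <- dx[dx$code %in% vocab, , drop = FALSE]

  ids <- unique(dx$id)
  x <- Matrix::sparseMatrix(
    i = match(dx$id, ids),
    j = match(dx$code, vocab),
    x = 1,
    dims = c(length(ids), length(vocab)),
    dimnames = list(NULL, vocab)
  )
  counts <- Matrix::crossprod(x)
  Matrix::diag(counts) <- 0
  counts <- Matrix::drop0(counts)

  structure(
    list(
      vocabulary = vocab,
      counts = counts,
      profile_counts = setNames(as.integer(freq[vocab]), vocab),
      n_profiles = length(ids)
    ),
    class = "franklin_cooccurrence"
  )
}

#' Train code embeddings from a co-occurrence matrix
#'
#' Default method: positive pointwise-mutual-information (PPMI) transform of
#' the pair counts, treated as a similarity kernel, followed by a rank-`d`
#' truncated eigendecomposition restricted to positive eigenvalues (the
#' kernel's positive-semidefinite part). Embedding rows are
#' `V_d diag(lambda_d^alpha)`, so with `alpha = 0.5` inner products of
#' embeddings reconstruct the PSD part of the PPMI matrix and cosine
#' similarity directly reflects co-occurrence strength. The factorization
#' is exact (LAPACK) and therefore deterministic; eigenvector signs are
#' fixed so the largest-magnitude loading in each dimension is positive.
#'
#' @param cooc A `franklin_cooccurrence`.
#' @param d Embedding dimension (default 50); clipped (with a warning) to
#'   `vocabulary - 1` or to the number of positive eigenvalues, whichever
#'   binds first.
#' @param alpha Eigenvalue weighting exponent (default 0.5).
#' @return A list of class `franklin_embeddings` with `vectors` (matrix,
#'   rows named by code), `d`, `alpha` and training metadata.
#' @export
train_embeddings <- function(cooc, d = 50L, alpha = 0.5) {
  stopifnot(inherits(cooc, "franklin_cooccurrence"))
  v <- length(cooc$vocabulary)
  if (v == 0) abort("empty vocabulary.")
  check_number(d, "d", min = 1, integerish = TRUE)
  if (d > v - 1 && v > 1) {
    warn(sprintf("d=%d exceeds vocabulary-1=%d; clipping.", d, v - 1))
    d <- v - 1L
  }
  d <- as.integer(max(1L, min(d, v)))

  ppmi <- ppmi_matrix(cooc$counts)
  eig <- eigen(ppmi, symmetric = TRUE)
  pos <- which(eig$values > 1e-10)
  if (length(pos) == 0) {
    # no positive part (e.g. no co-occurrence at all): zero embeddings
    vectors <- matrix(0, v, d)
    lambda <- rep(0, d)
  } else {
    keep <- pos[seq_len(min(d, length(pos)))]
    u <- eig$vectors[, keep, drop = FALSE]
    for (j in seq_along(keep)) {
      if (u[which.max(abs(u[, j])), j] < 0) u[, j] <- -u[, j]
    }
    lambda <- eig$values[keep]
    vectors <- u %*% diag(lambda^alpha, nrow = length(keep))
    if (ncol(vectors) < d) {
      # pad so the contract dimension is honored even for low-rank kernels
      vectors <- cbind(vectors,
                       matrix(0, v, d - ncol(vectors)))
      lambda <- c(lambda, rep(0, d - length(lambda)))
    }
  }
  rownames(vectors) <- cooc$vocabulary

  structure(
    list(
      vectors = vectors,
      d = d,
      alpha = alpha,
      eigenvalues = lambda,
      meta = list(n_profiles = cooc$n_profiles, vocabulary_size = v,
                  method = "ppmi_psd_eigen"),
      singular_values = lambda
    ),
    class = "franklin_embeddings"
  )
}

# PPMI transform: pmi_ij = log(c_ij * S / (r_i * r_j)) clipped below at 0,
# with S the total pair count and r the marginal row sums.
ppmi_matrix <- function(counts) {
  m <- as.matrix(counts)
  s <- sum(m)
  if (s == 0) return(matrix(0, nrow(m), ncol(m), dimnames = dimnames(m)))
  r <- rowSums(m)
  denom <- outer(r, r)
  pmi <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  nz <- m > 0 & denom > 0
  pmi[nz] <- log(m[nz] * s / denom[nz])
  pmi[pmi < 0] <- 0
  pmi
}

#' Cluster code embeddings with spherical k-means
#'
#' Runs k-means on length-normalized embedding rows (`n_init` restarts,
#' best within-cluster inertia kept), so that clustering is driven by
#' direction — the same geometry as the cosine similarity used for the
#' cluster features.
#'
#' @param embeddings A `franklin_embeddings`.
#' @param k Number of clusters (default 250); clipped to the vocabulary
#'   size with a warning.
#' @param seed Integer seed (restarts are seeded; identical seeds give
#'   identical centers).
#' @param n_init Number of random restarts.
#' @param iter_max Maximum Lloyd iterations per restart.
#' @return A list of class `franklin_clusters` with `centers` (k x d),
#'   `assignment` (named integer vector code -> cluster), `inertia`, `k`,
#'   `seed`.
#' @export
fit_clusters <- function(embeddings, k = 250L, seed = 1L, n_init = 10L,
                         iter_max = 100L) {
  stopifnot(inherits(embeddings, "franklin_embeddings"))
  check_number(k, "k", min = 2, integerish = TRUE)
  unit <- cosine_normalize_rows(embeddings$vectors)
  # kmeans cannot place more centers than there are distinct points; codes
  # with identical co-occurrence profiles share a direction, so clip to the
  # number of distinct unit vectors.
  v_distinct <- nrow(unique(round(unit, 12)))
  if (k > v_distinct) {
    warn(sprintf("k=%d exceeds the %d distinct embedding directions; clipping.",
                 k, v_distinct))
    k <- v_distinct
  }
  if (k == v_distinct) {
    # degenerate singleton clustering: every distinct direction its own center
    centers <- unique(round(unit, 12))
    key <- apply(round(unit, 12), 1, paste, collapse = ",")
    ckey <- apply(centers, 1, paste, collapse = ",")
    cluster <- match(key, ckey)
    inertia <- sum((unit - centers[cluster, , drop = FALSE])^2)
    fit <- list(centers = centers, cluster = cluster, tot.withinss = inertia)
  } else {
    fit <- with_seed(seed, kmeans(unit, centers = k, nstart = n_init,
                                  iter.max = iter_max))
  }
  structure(
    list(
      centers = fit$centers,
      assignment = setNames(as.integer(fit$cluster), rownames(unit)),
      inertia = fit$tot.withinss,
      k = as.integer(k),
      seed = as.integer(seed)
    ),
    class = "franklin_clusters"
  )
}

#' Maximum-similarity cluster features per beneficiary
#'
#' For each beneficiary, feature `j` is the maximum cosine similarity
#' between any of their in-vocabulary code embeddings and cluster center
#' `j`. Out-of-vocabulary codes are ignored; a beneficiary with no
#' in-vocabulary codes gets an all-zero feature vector. A single code can
#' contribute to several clusters, so assignment to categories is
#' fractional rather than exclusive.
#'
#' @param cohort Beneficiary tibble (`id`, ...); defines the row order.
#' @param diagnoses Long diagnosis tibble (`id`, `code`).
#' @param embeddings A `franklin_embeddings`.
#' @param clusters A `franklin_clusters`.
#' @return Tibble with `id` plus `k` feature columns `cluster_001`, ...;
#'   entries lie in [-1, 1].
#' @export
compute_cluster_features <- function(cohort, diagnoses, embeddings, clusters) {
  stopifnot(inherits(embeddings, "franklin_embeddings"),
            inherits(clusters, "franklin_clusters"))
  k <- clusters$k
  sim <- cosine_normalize_rows(embeddings$vectors) %*%
    t(cosine_normalize_rows(clusters$centers))

  dx <- diagnoses[diagnoses$code %in% rownames(sim), , drop = FALSE]
  rows_by_id <- split(match(dx$code, rownames(sim)), dx$id)
  feat <- matrix(0, nrow = nrow(cohort), ncol = k)
  hit <- match(cohort$id, names(rows_by_id))
  for (i in which(!is.na(hit))) {
    idx <- rows_by_id[[hit[i]]]
    feat[i, ] <- if (length(idx) == 1L) sim[idx, ] else
      apply(sim[idx, , drop = FALSE], 2, max)
  }
  colnames(feat) <- sprintf("cluster_%03d", seq_len(k))
  dplyr::bind_cols(tibble(id = cohort$id), as_tibble(feat))
}

#' Bootstrap stability of the embedding-and-cluster partition
#'
#' Refits embeddings and clusters on bootstrap resamples of the profile set
#' and reports the mean pairwise adjusted Rand agreement between the code
#' partitions (restricted to codes present in every resample vocabulary).
#'
#' @param diagnoses Long diagnosis tibble for the embeddings split.
#' @param n_boot Number of bootstrap refits (at least 2).
#' @param d,k,min_count Embedding/cluster parameters.
#' @param seed Integer seed.
#' @param resample If `FALSE`, every refit uses the full profile set
#'   (agreement is then exactly 1; useful as a determinism check).
#' @return A list with `mean_agreement`, `pairwise` (tibble of pairwise
#'   adjusted Rand indices) and `n_common_codes`.
#' @export
cluster_stability <- function(diagnoses, n_boot = 5L, d = 20L, k = 10L,
                              min_count = 5L, seed = 1L, resample = TRUE) {
  check_number(n_boot, "n_boot", min = 2, integerish = TRUE)
  ids <- unique(diagnoses$id)
  codes_by_id <- split(diagnoses$code, factor(diagnoses$id, levels = ids))
  partitions <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      take <- if (resample) sample(ids, length(ids), replace = TRUE) else ids
      # Resampled profiles are distinct documents even when the same id is
      # drawn twice, so re-key them.
      picked <- codes_by_id[take]
      dx <- tibble(
        id = rep(sprintf("bs%05d", seq_along(picked)), lengths(picked)),
        code = unlist(picked, use.names = FALSE)
      )
      cooc <- build_cooccurrence(dx, min_count = min_count)
      emb <- suppressWarnings(train_embeddings(cooc, d = d))
      cl <- suppressWarnings(fit_clusters(emb, k = k, seed = seed + b))
      cl$assignment
    })
  })
  common <- Reduce(intersect, lapply(partitions, names))
  pairs <- utils::combn(n_boot, 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    a <- partitions[[pairs[1, p]]][common]
    b <- partitions[[pairs[2, p]]][common]
    tibble(boot_a = pairs[1, p], boot_b = pairs[2, p],
           agreement = adjusted_rand_index(a, b))
  })
  list(
    mean_agreement = mean(pw$agreement),
    pairwise = pw,
    n_common_codes = length(common)
  )
}
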