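# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the package internals.

# Closed-form two-class Fisher discriminant: classify to class `a` when
# w'(x - midpoint) > 0 with w = Sw^-1 (mu_a - mu_b); ties go to class a
# (the lower label).
oracle_lda2 <- function(Xtrain, ytrain, Xtest) {
  classes <- sort(unique(ytrain))
  stopifnot(length(classes) == 2L)
  Xa <- Xtrain[ytrain == classes[1L], , drop = FALSE]
  Xb <- Xtrain[ytrain == classes[2L], , drop = FALSE]
  mu_a <- colMeans(Xa); mu_b <- colMeans(Xb)
  Sw <- ((nrow(Xa) - 1) * cov(Xa) + (nrow(Xb) - 1) * cov(Xb)) /
    (nrow(Xtrain) - 2)
  w <- solve(Sw, mu_a - mu_b)
  score <- as.vector(Xtest %*% w) - sum(w * (mu_a + mu_b)) / 2
  ifelse(score >= 0, classes[1L], classes[2L])
}

# Brute-force group-average agglomeration: cluster distances recomputed from
# the original distance matrix at every step as the plain mean over all
# cross-cluster member pairs; ties broken by the lexicographically smallest
# (min leaf, max leaf) pair. Returns merge heights and the cophenetic matrix.
oracle_upgma <- function(Dm) {
  n <- nrow(Dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1L)
  coph <- matrix(0, n, n)
  for (step in seq_len(n - 1L)) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      dij <- mean(Dm[clusters[[i]], clusters[[j]]])
      key <- c(dij, min(min(clusters[[i]]), min(clusters[[j]])),
               max(min(clusters[[i]]), min(clusters[[j]])))
      if (is.null(best) ||
          key[1L] < best$key[1L] - 1e-12 ||
          (abs(key[1L] - best$key[1L]) <= 1e-12 &&
           (key[2L] < best$key[2L] ||
            (key[2L] == best$key[2L] && key[3L] < best$key[3L]))))
        best <- list(key = key, i = i, j = j)
    }
    heights[step] <- best$key[1L]
    a <- clusters[[best$i]]; b <- clusters[[best$j]]
    coph[a, b] <- best$key[1L]; coph[b, a] <- best$key[1L]
    clusters <- c(clusters[-c(best$i, best$j)], list(c(a, b)))
  }
  list(heights = heights, cophenetic = coph)
}

# Exact upper-tail binomial probability by direct summation of the pmf.
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(dbinom(seq.int(k, n), n, p))
}

# Smallest correct count whose CDF reaches 1 - alpha, by direct summation.
oracle_threshold_count <- function(n, p, alpha) {
  cdf <- cumsum(dbinom(0:n, n, p))
  (0:n)[which(cdf >= 1 - alpha - 1e-12)[1L]]
}

# Exact two-tailed rank-sum p-value by exhaustive enumeration of all
# assignments of the pooled values to the first group (tie-free data).
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  splits <- combn(length(pooled), length(x))
  U_all <- apply(splits, 2L, function(idx)
    sum(r[idx]) - length(x) * (length(x) + 1) / 2)
  p <- 2 * min(mean(U_all <= U_obs), mean(U_all >= U_obs))
  min(p, 1)
}

# Small well-separated two-class dataset for sanity checks.
make_separable_ds <- function(n_per_class = 20, seed = 1) {
  cfg <- generator_config(n_electrodes = 4, n_time_samples = 4,
                          n_categories = 2, n_exemplars_per_category = 1,
                          n_trials_per_exemplar = n_per_class,
                          var_category = 50, var_noise = 0.01, seed = seed)
  simulate_dataset(cfg)
}
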