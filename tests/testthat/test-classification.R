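test_that("SVD rotation satisfies the decomposition identities", {
  set.seed(11)
  X <- matrix(rnorm(30 * 8), 30, 8)
  cs <- svd_rotate(X)
  # reconstruction
  expect_lt(norm(cs$rotated %*% t(cs$basis) - X, "F") / norm(X, "F"), 1e-10)
  # rotated equals X V
  expect_equal(X %*% cs$basis, cs$rotated, tolerance = 1e-10)
  # singular values nonincreasing, nonnegative
  expect_true(all(diff(cs$singular_values) <= 1e-12))
  expect_true(all(cs$singular_values >= 0))
  # deterministic sign convention
  expect_identical(cs$basis, svd_rotate(X)$basis)
  for (j in seq_len(ncol(cs$basis))) {
    col <- cs$basis[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }

  # rank-1 input has exactly one singular value above tolerance
  X1 <- outer(rnorm(20), rnorm(5))
  sv <- svd_rotate(X1)$singular_values
  expect_equal(sum(sv > 1e-10 * sv[1]), 1)

  # orthogonal rows with distinct norms: the rotation aligns each trial
  # with its own component, so rotated rows are axis-aligned with the row
  # norms as the singular values
  Q <- diag(c(4, 3, 2, 1)) %*% t(qr.Q(qr(matrix(rnorm(16), 4, 4))))
  rq <- svd_rotate(Q)
  expect_equal(rq$singular_values, c(4, 3, 2, 1), tolerance = 1e-10)
  expect_equal(apply(abs(rq$rotated), 1L, max),
               sqrt(rowSums(Q^2)), tolerance = 1e-10)
  expect_equal(rq$rotated %*% t(rq$rotated), Q %*% t(Q), tolerance = 1e-9)

  X[2, 3] <- NA
  expect_error(svd_rotate(X), "non-finite")
})

test_that("one-vs-rest LDA matches the closed-form two-class discriminant", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    p <- sample(2:5, 1)
    shift <- runif(1, 0.5, 3)
    y <- rep(1:2, length.out = n)
    X <- matrix(rnorm(n * p), n, p) + outer(ifelse(y == 1, shift, 0), rep(1, p))
    Xtest <- matrix(rnorm(20 * p), 20, p) + shift / 2
    model <- lda_fit(X, y)
    expect_equal(lda_predict(model, Xtest), oracle_lda2(X, y, Xtest))
  }
})

test_that("LDA agrees with an established reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(33)
  n <- 60; p <- 4
  y <- rep(1:2, each = n / 2)
  X <- matrix(rnorm(n * p), n, p) + outer(ifelse(y == 1, 1.2, 0), rep(1, p))
  Xtest <- matrix(rnorm(40 * p), 40, p) + 0.6
  mine <- lda_predict(lda_fit(X, y), Xtest)
  ref <- as.integer(predict(MASS::lda(X, grouping = y), Xtest)$class)
  expect_equal(mine, ref)
})

test_that("LDA degenerate inputs and tie-breaking behave as documented", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(lda_fit(X, rep(1, 10)), "2 classes")
  expect_error(lda_fit(X, c(1, rep(2, 9))), "2 training trials")
  # singular pooled covariance advises shrinkage
  Xs <- cbind(rep(c(0, 1), each = 4), rep(c(0, 1), each = 4))
  expect_error(lda_fit(Xs, rep(1:2, each = 4)), "shrinkage")
  expect_s3_class(lda_fit(Xs, rep(1:2, each = 4), shrinkage = 0.1),
                  "lda_model")

  # symmetric means, isotropic covariance: boundary passes through origin,
  # and an exact score tie goes to the lowest class index
  model <- lda_fit(rbind(c(1, 1), c(2, 2), c(-1, -1), c(-2, -2)),
                   c(1, 1, 2, 2), shrinkage = 0.5)
  expect_lt(abs(sum(model$bias)), 1e-10)
  expect_equal(lda_predict(model, matrix(0, 1, 2)), 1)

  # a point at a well-separated class mean is assigned that class
  set.seed(2)
  Z <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 10), 20, 2))
  y <- rep(1:2, each = 20)
  expect_equal(lda_predict(lda_fit(Z, y), matrix(10, 1, 2)), 2)
})

test_that("nested component selection finds planted low-rank signal", {
  hits <- 0L
  for (s in 1:5) {
    set.seed(s)
    n <- 120
    y <- rep(1:2, length.out = n)
    # class signal lives entirely in the first 3 columns
    Z <- cbind(matrix(rnorm(n * 3, mean = ifelse(y == 1, 1.2, 0)), n, 3),
               matrix(rnorm(n * 22), n, 22))
    sel <- select_components_nested(Z, y, cv_config(), k_grid = c(3L, 25L))
    if (sel$k == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 3L)  # majority over seeds

  # pure noise: ties and near-ties resolve to the smallest k deterministically
  set.seed(7)
  Z0 <- matrix(rnorm(40 * 6), 40, 6)
  y0 <- rep(1:2, 20)
  set.seed(1); k1 <- select_components_nested(Z0, y0, cv_config(), c(3L, 6L))$k
  set.seed(1); k2 <- select_components_nested(Z0, y0, cv_config(), c(3L, 6L))$k
  expect_identical(k1, k2)
})

test_that("confusion matrices respect the counting invariants", {
  cm <- confusion_matrix(matrix(c(8, 2, 3, 7), 2, byrow = TRUE), c("a", "b"))
  expect_equal(rowSums(cm$normalized), c(a = 1, b = 1))
  expect_equal(cm$accuracy, mean(c(0.8, 0.7)))
  expect_error(confusion_matrix(matrix(1:6, 2, 3)), "square")
  expect_error(confusion_matrix(matrix(c(1, -1, 0, 2), 2)), "negative")
})

test_that("cross-validation tests every trial once and aggregates correctly", {
  ds <- make_separable_ds(20, seed = 3)
  res <- crossvalidate(ds, "category", cv_config(seed = 3, k_grid = c(3L, 8L)))
  # counts conservation
  expect_equal(sum(res$confusion$counts), 40)
  expect_equal(unname(rowSums(res$confusion$counts)), c(20, 20))
  expect_equal(sum(res$fold_size), 40)
  expect_equal(sum(res$fold_correct),
               sum(diag(res$confusion$counts)))
  # perfectly separable two-class toy: identity confusion
  expect_equal(unname(res$confusion$normalized), diag(2))
  # determinism under the same seed
  res2 <- crossvalidate(ds, "category", cv_config(seed = 3, k_grid = c(3L, 8L)))
  expect_identical(res$confusion$counts, res2$confusion$counts)
  expect_identical(res$fold_k, res2$fold_k)
})

test_that("outer fold sizes follow the floor(n/folds) + remainder rule", {
  folds <- eegrsa:::make_folds(5184, 10)
  expect_equal(unname(table(folds)), rep(c(519, 518), c(4, 6)),
               ignore_attr = TRUE)
  expect_equal(sum(table(folds)), 5184)
  folds2 <- eegrsa:::make_folds(40, 10)
  expect_true(all(table(folds2) == 4))
})

test_that("shuffled labels decode at chance level", {
  cfg <- generator_config(n_electrodes = 4, n_time_samples = 8,
                          n_exemplars_per_category = 1,
                          n_trials_per_exemplar = 30,
                          var_category = 5, var_noise = 1, seed = 12)
  ds <- simulate_dataset(cfg)
  set.seed(99)
  ds_null <- trialspace_dataset(ds$X1, seq_len(nrow(ds$X1)),
                                sample(ds$category_labels),
                                ds$n_electrodes, ds$n_time_samples)
  res <- crossvalidate(ds_null, "category",
                       cv_config(seed = 42, k_grid = c(3L, 6L)))
  n <- nrow(ds$X1)
  band <- qbinom(c(0.005, 0.995), n, 1 / 6)
  correct <- sum(diag(res$confusion$counts))
  expect_gte(correct, band[1])
  expect_lte(correct, band[2])
})

test_that("unbalanced class counts are rejected unless explicitly allowed", {
  ds <- make_separable_ds(20, seed = 5)
  dsu <- trialspace_dataset(ds$X1[-1, ], ds$exemplar_labels[-1],
                            ds$category_labels[-1], 4, 4)
  expect_error(crossvalidate(dsu, "category", cv_config(seed = 1)),
               "unbalanced")
  expect_s3_class(crossvalidate(dsu, "category",
                                cv_config(seed = 1, k_grid = c(3L, 8L)),
                                allow_unbalanced = TRUE),
                  "decoding_result")
})
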