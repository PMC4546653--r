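#' Cross-validation configuration for the decoder
#'
#' Controls the ten-fold outer cross-validation and the nested ten-fold inner
#' cross-validation in which the number of principal components is selected.
#' The candidate component counts `k_grid` default to every integer in
#' `[k_min, min(200, K)]` when the feature vector is short (`K <= 32`), and to
#' a 24-point log-spaced grid over the same range otherwise.
#'
#' @param n_folds_outer,n_folds_inner fold counts (defaults 10 and 10).
#' @param k_min,k_max bounds on the number of principal components; `k_max`
#'   defaults to `min(200, K)` at fit time when `NULL`.
#' @param k_grid explicit candidate list (sorted, within bounds); overrides
#'   the default grid.
#' @param seed RNG seed controlling fold assignment.
#' @param stratified assign folds within class rather than by a plain random
#'   permutation of all trials (default `FALSE`).
#' @param shrinkage nonnegative ridge added to the diagonal of the pooled
#'   within-class covariance (default 0).
#' @param fold_safe_svd recompute the SVD on each outer training fold rather
#'   than once on the full matrix (default `FALSE`; see Details).
#' @details With `fold_safe_svd = FALSE` the principal-component basis is
#'   computed once from the full trial matrix before partitioning — cheaper,
#'   and the convention this pipeline reproduces — at the cost of sharing
#'   unsupervised structure between training and test folds. Setting it to
#'   `TRUE` restricts the SVD to each outer training fold.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(n_folds_outer = 10, n_folds_inner = 10,
                      k_min = 3, k_max = NULL, k_grid = NULL,
                      seed = 1L, stratified = FALSE, shrinkage = 0,
                      fold_safe_svd = FALSE) {
  if (n_folds_outer < 2 || n_folds_inner < 2) stop("fold counts must be >= 2")
  if (k_min < 1) stop("k_min must be >= 1")
  if (shrinkage < 0) stop("shrinkage must be >= 0")
  if (!is.null(k_grid)) {
    k_grid <- as.integer(k_grid)
    if (length(k_grid) == 0L || is.unsorted(k_grid))
      stop("k_grid must be non-empty and sorted")
  }
  structure(list(n_folds_outer = as.integer(n_folds_outer),
                 n_folds_inner = as.integer(n_folds_inner),
                 k_min = as.integer(k_min),
                 k_max = if (!is.null(k_max)) as.integer(k_max),
                 k_grid = k_grid, seed = as.integer(seed),
                 stratified = stratified, shrinkage = shrinkage,
                 fold_safe_svd = fold_safe_svd),
            class = "cv_config")
}

default_k_grid <- function(cfg, K, rank) {
  kmax <- min(if (is.null(cfg$k_max)) min(200L, K) else cfg$k_max, rank)
  kmin <- min(cfg$k_min, kmax)
  if (!is.null(cfg$k_grid)) {
    grid <- cfg$k_grid[cfg$k_grid <= kmax]
    if (length(grid) < length(cfg$k_grid))
      warning("k_grid truncated to available rank (k <= ", kmax, ")")
    if (length(grid) == 0L) grid <- kmax
    return(grid)
  }
  if (K <= 32L) return(seq.int(kmin, kmax))
  unique(round(exp(seq(log(kmin), log(kmax), length.out = 24L))))
}

#' Rotate a trial-space matrix into component space
#'
#' Principal component analysis by thin singular value decomposition:
#' `X1 = U S V'`, rotated coordinates `X1 V = U S`. Components are ordered by
#' descending singular value; each basis column's sign is fixed so that its
#' largest-magnitude entry is positive, making the rotation deterministic.
#'
#' @param X1 numeric matrix (trials x features) or a `trialspace_dataset`.
#' @return An object of class `component_space` with `rotated` (`U S`),
#'   `basis` (`V`) and `singular_values`.
#' @export
svd_rotate <- function(X1) {
  if (inherits(X1, "trialspace_dataset")) X1 <- X1$X1
  if (!all(is.finite(X1))) stop("non-finite entries in data matrix")
  if (nrow(X1) < 2L) stop("need at least 2 trials")
  sv <- tryCatch(svd(X1), error = function(e)
    stop("SVD did not converge in the computation of principal components: ",
         conditionMessage(e)))
  # deterministic sign: largest-|.| entry of each basis column positive
  flip <- vapply(seq_len(ncol(sv$v)), function(j) {
    col <- sv$v[, j]
    sign(col[which.max(abs(col))])
  }, numeric(1L))
  flip[flip == 0] <- 1
  v <- sweep(sv$v, 2L, flip, `*`)
  u <- sweep(sv$u, 2L, flip, `*`)
  structure(list(rotated = u %*% diag(sv$d, length(sv$d)),
                 basis = v, singular_values = sv$d),
            class = "component_space")
}

#' Fit a one-against-all linear discriminant model
#'
#' For each class `c`, fits the two-class Fisher discriminant of class `c`
#' against all remaining trials pooled: weight vector
#' `w_c = S_w^-1 (mu_c - mu_rest)` with `S_w` the pooled within-group
#' covariance (plus `shrinkage` on the diagonal), and bias placing the
#' decision boundary at the midpoint of the two group means. Multi-class
#' prediction is the argmax of the per-class discriminant scores.
#'
#' @param Z numeric matrix of component scores (trials x k); only the first
#'   `k` columns are used.
#' @param y class labels (length `nrow(Z)`).
#' @param k number of leading components to use (default all columns).
#' @param shrinkage nonnegative diagonal ridge on the pooled covariance.
#' @return An object of class `lda_model`: `weights` (k x nClasses), `bias`,
#'   `classes`, `k`.
#' @export
lda_fit <- function(Z, y, k = ncol(Z), shrinkage = 0) {
  Z <- as.matrix(Z)
  if (k > ncol(Z)) stop("k exceeds available components")
  Z <- Z[, seq_len(k), drop = FALSE]
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least 2 classes to fit a discriminant")
  if (any(table(y) < 2L)) stop("every class needs at least 2 training trials")
  n <- nrow(Z)
  W <- matrix(0, k, length(classes))
  b <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    in_c <- y == classes[ci]
    Zc <- Z[in_c, , drop = FALSE]; Zr <- Z[!in_c, , drop = FALSE]
    mu_c <- colMeans(Zc); mu_r <- colMeans(Zr)
    Sw <- ((nrow(Zc) - 1L) * stats::cov(Zc) +
           (nrow(Zr) - 1L) * stats::cov(Zr)) / (n - 2L)
    if (shrinkage > 0) Sw <- Sw + diag(shrinkage, k)
    w <- tryCatch(solve(Sw, mu_c - mu_r), error = function(e)
      stop("singular pooled covariance; increase k_min, reduce k, ",
           "or set a positive shrinkage"))
    W[, ci] <- w
    b[ci] <- -sum(w * (mu_c + mu_r)) / 2
  }
  structure(list(weights = W, bias = b, classes = classes, k = k),
            class = "lda_model")
}

#' Predict class labels from a one-against-all LDA model
#'
#' Scores each trial against every class discriminant and returns the argmax;
#' exact ties are broken toward the lowest class index, deterministically.
#'
#' @param model an [lda_fit()] result.
#' @param Z component-score matrix with at least `model$k` columns (the first
#'   `model$k` are used).
#' @return vector of predicted labels, one per row of `Z`.
#' @export
lda_predict <- function(model, Z) {
  stopifnot(inherits(model, "lda_model"))
  Z <- as.matrix(Z)
  if (ncol(Z) < model$k) stop("Z has fewer columns than the model's k")
  scores <- Z[, seq_len(model$k), drop = FALSE] %*% model$weights
  scores <- sweep(scores, 2L, model$bias, `+`)
  # max.col with ties.method = "first" = lowest class index on exact ties
  model$classes[max.col(scores, ties.method = "first")]
}

# fold assignment: random permutation split into n_folds contiguous blocks,
# sizes floor(n/folds) with the remainder going to the first n %% folds folds
make_folds <- function(n, n_folds, stratified = FALSE, y = NULL) {
  sizes <- rep(n %/% n_folds, n_folds)
  if (n %% n_folds > 0L) sizes[seq_len(n %% n_folds)] <- sizes[seq_len(n %% n_folds)] + 1L
  fold <- integer(n)
  if (stratified) {
    stopifnot(!is.null(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep.int(seq_len(n_folds), sizes)
  }
  fold
}

#' Select the number of principal components by nested cross-validation
#'
#' Evaluates every candidate `k` by `n_folds_inner`-fold cross-validation on
#' the training data alone and returns the candidate with the highest mean
#' inner-fold accuracy; ties go to the smallest `k` (parsimony).
#'
#' @param Ztrain training-trial component scores (rows x components).
#' @param ytrain training labels.
#' @param cfg a [cv_config()].
#' @param k_grid candidate component counts; defaults to the grid implied by
#'   `cfg` and the matrix dimensions.
#' @return list with `k` (the selected count) and `accuracy` (mean inner
#'   accuracy per grid value).
#' @export
select_components_nested <- function(Ztrain, ytrain, cfg = cv_config(),
                                     k_grid = NULL) {
  Ztrain <- as.matrix(Ztrain)
  if (is.null(k_grid))
    k_grid <- default_k_grid(cfg, ncol(Ztrain), ncol(Ztrain))
  fold <- make_folds(nrow(Ztrain), cfg$n_folds_inner, cfg$stratified, ytrain)
  correct <- numeric(length(k_grid))
  for (f in seq_len(cfg$n_folds_inner)) {
    test <- fold == f
    for (gi in seq_along(k_grid)) {
      model <- lda_fit(Ztrain[!test, , drop = FALSE], ytrain[!test],
                       k = k_grid[gi], shrinkage = cfg$shrinkage)
      pred <- lda_predict(model, Ztrain[test, , drop = FALSE])
      correct[gi] <- correct[gi] + sum(pred == ytrain[test])
    }
  }
  acc <- correct / nrow(Ztrain)
  list(k = k_grid[which.max(acc)], accuracy = stats::setNames(acc, k_grid))
}

#' Construct a confusion matrix object from counts
#'
#' @param counts square matrix of nonnegative integers; rows are actual
#'   labels, columns predicted labels.
#' @param classes class labels in row/column order.
#' @return An object of class `confusion_matrix` with `counts`, the
#'   row-stochastic `normalized` form, `classes`, and `accuracy` (mean of the
#'   normalized diagonal; with balanced classes this equals the fraction of
#'   correct classifications).
#' @export
confusion_matrix <- function(counts, classes = seq_len(nrow(counts))) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("confusion counts must be square")
  if (any(counts < 0)) stop("negative confusion counts")
  rs <- rowSums(counts)
  if (any(rs == 0)) stop("a class has no test trials")
  normalized <- counts / rs
  dimnames(counts) <- dimnames(normalized) <- list(classes, classes)
  structure(list(counts = counts, normalized = normalized,
                 classes = classes, accuracy = mean(diag(normalized))),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix over %d classes; accuracy %.2f%%\n",
              length(x$classes), 100 * x$accuracy))
  print(round(x$normalized, 3), ...)
  invisible(x)
}

#' Cross-validated multi-class decoding of a trial-space dataset
#'
#' The decoding core: rotates the trial matrix into principal-component space
#' by SVD, partitions trials into `n_folds_outer` random folds, and within
#' each fold selects the number of components by nested inner
#' cross-validation on the training partitions before fitting the
#' one-against-all LDA and predicting the held-out fold. Every trial is
#' tested exactly once; predictions are aggregated into a single confusion
#' matrix.
#'
#' By default the SVD is computed once on the full matrix before
#' partitioning (see [cv_config()]'s `fold_safe_svd`).
#'
#' @param ds a `trialspace_dataset`.
#' @param level `"category"` or `"exemplar"`: which labels to decode.
#' @param cfg a [cv_config()].
#' @param allow_unbalanced permit unequal class counts (default `FALSE`:
#'   decoding assumes balanced designs, where chance = 1/nClasses and the
#'   normalized-diagonal mean equals overall accuracy).
#' @return An object of class `decoding_result`: `confusion`
#'   (a [confusion_matrix()]), `fold_k` (selected components per fold),
#'   `fold_correct` and `fold_size` (per-fold correct counts and test-fold
#'   sizes), `level`, `n_folds`.
#' @export
crossvalidate <- function(ds, level = c("category", "exemplar"),
                          cfg = cv_config(), allow_unbalanced = FALSE) {
  stopifnot(inherits(ds, "trialspace_dataset"))
  level <- match.arg(level)
  y <- if (level == "category") ds$category_labels else ds$exemplar_labels
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least 2 classes to decode")
  tab <- table(y)
  if (!allow_unbalanced && length(unique(as.integer(tab))) != 1L)
    stop("unbalanced class counts; set allow_unbalanced = TRUE to proceed")
  n <- nrow(ds$X1)
  K <- ncol(ds$X1)

  withr_seed(cfg$seed, {
    full_cs <- if (!cfg$fold_safe_svd) svd_rotate(ds$X1)
    fold <- make_folds(n, cfg$n_folds_outer, cfg$stratified, y)
    counts <- matrix(0L, length(classes), length(classes))
    fold_k <- integer(cfg$n_folds_outer)
    fold_correct <- integer(cfg$n_folds_outer)
    fold_size <- integer(cfg$n_folds_outer)
    for (f in seq_len(cfg$n_folds_outer)) {
      test <- fold == f
      if (cfg$fold_safe_svd) {
        cs <- svd_rotate(ds$X1[!test, , drop = FALSE])
        Ztrain <- cs$rotated
        Ztest <- ds$X1[test, , drop = FALSE] %*% cs$basis
        rank <- sum(cs$singular_values > 1e-10 * cs$singular_values[1L])
      } else {
        Ztrain <- full_cs$rotated[!test, , drop = FALSE]
        Ztest <- full_cs$rotated[test, , drop = FALSE]
        rank <- sum(full_cs$singular_values >
                      1e-10 * full_cs$singular_values[1L])
      }
      k_grid <- default_k_grid(cfg, K, rank)
      sel <- select_components_nested(Ztrain, y[!test], cfg, k_grid)
      model <- lda_fit(Ztrain, y[!test], k = sel$k, shrinkage = cfg$shrinkage)
      pred <- lda_predict(model, Ztest)
      actual <- y[test]
      for (i in seq_along(pred)) {
        ai <- match(actual[i], classes); pi <- match(pred[i], classes)
        counts[ai, pi] <- counts[ai, pi] + 1L
      }
      fold_k[f] <- sel$k
      fold_correct[f] <- sum(pred == actual)
      fold_size[f] <- sum(test)
    }
    structure(list(confusion = confusion_matrix(counts, classes),
                   fold_k = fold_k, fold_correct = fold_correct,
                   fold_size = fold_size, level = level,
                   n_folds = cfg$n_folds_outer),
              class = "decoding_result")
  })
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(paste0(
    "%s-level decoding: %d classes, %d trials, %d-fold CV\n",
    "  accuracy %.2f%% (chance %.2f%%); components per fold: %s\n"),
    x$level, length(x$confusion$classes), sum(x$confusion$counts), x$n_folds,
    100 * x$confusion$accuracy, 100 / length(x$confusion$classes),
    paste(x$fold_k, collapse = " ")))
  invisible(x)
}
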