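#' Exact binomial inference on cross-validated accuracy
#'
#' Significance of a classifier's accuracy under the null hypothesis that
#' every test classification is an independent Bernoulli trial at chance
#' level. Following the per-fold convention, the test statistic is the
#' floored mean number of correct classifications in one test fold,
#' `cFold = floor(totalCorrect / nFolds)`, out of
#' `nFold = floor(nTrials / nFolds)` attempts: the p-value is the exact
#' upper tail `P(X >= cFold)` for `X ~ Binomial(nFold, chance)`, and the
#' effect size `d = (cFold - C0) / sigma` counts null standard deviations
#' between the observed and expected correct counts, with
#' `C0 = nFold * chance` and `sigma = sqrt(nFold * chance * (1 - chance))`.
#'
#' @param total_correct total correct classifications over all folds.
#' @param n_trials total classifications attempted (all folds).
#' @param n_folds number of cross-validation folds (default 10).
#' @param chance chance-level accuracy, 1/nClasses for balanced designs.
#' @return An object of class `binomial_report`: `n_fold`, `c_fold`,
#'   `chance`, `p_value`, `C0`, `sigma`, `d`, `accuracy`.
#' @export
binomial_pvalue <- function(total_correct, n_trials, n_folds = 10,
                            chance) {
  if (chance <= 0 || chance >= 1) stop("chance must lie in (0, 1)")
  if (total_correct < 0 || total_correct > n_trials)
    stop("total_correct must lie in [0, n_trials]")
  if (n_folds < 1) stop("n_folds must be >= 1")
  n_fold <- floor(n_trials / n_folds)
  c_fold <- floor(total_correct / n_folds)
  p <- stats::pbinom(c_fold - 1, n_fold, chance, lower.tail = FALSE)
  C0 <- n_fold * chance
  sigma <- sqrt(n_fold * chance * (1 - chance))
  structure(list(n_fold = n_fold, c_fold = c_fold, chance = chance,
                 p_value = p, C0 = C0, sigma = sigma,
                 d = (c_fold - C0) / sigma,
                 accuracy = total_correct / n_trials),
            class = "binomial_report")
}

#' @export
print.binomial_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Accuracy %.2f%% (chance %.2f%%); per-fold %d/%d correct\n",
    "  exact binomial p = %.3g, effect size d = %.2f\n"),
    100 * x$accuracy, 100 * x$chance, x$c_fold, x$n_fold, x$p_value, x$d))
  invisible(x)
}

#' Accuracy threshold for statistical significance
#'
#' The smallest accuracy (as a display percentage) that is significant at
#' level `alpha` under the per-fold binomial null: with
#' `nFold = floor(nTrials / nFolds)` attempts per fold, finds the smallest
#' correct count `k` whose exact binomial CDF reaches `1 - alpha` (the exact
#' upper quantile) and reports `100 * k / nFold` rounded to two decimals.
#'
#' @param n_trials,n_folds total classifications and fold count.
#' @param chance chance-level accuracy.
#' @param alpha significance level (default 0.01).
#' @return threshold accuracy in percent, rounded to 2 decimals.
#' @export
significance_threshold <- function(n_trials, n_folds = 10, chance,
                                   alpha = 0.01) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (chance <= 0 || chance >= 1) stop("chance must lie in (0, 1)")
  n_fold <- floor(n_trials / n_folds)
  k <- stats::qbinom(1 - alpha, n_fold, chance)
  round(100 * k / n_fold, 2)
}

#' Unbiased sample standard deviation across participants
#'
#' Square root of the variance with the `n - 1` denominator; the dispersion
#' measure reported alongside cross-participant mean accuracies.
#'
#' @param x numeric vector of per-participant accuracies (length >= 2).
#' @return the sample standard deviation.
#' @export
sample_std <- function(x) {
  if (length(x) < 2L) stop("need at least 2 participants")
  stats::sd(x)
}

#' Category separability along MDS dimensions by rank-sum tests
#'
#' For every unordered pair of categories and every requested embedding
#' dimension, tests whether the two categories' exemplar coordinates along
#' that dimension differ, using the two-tailed Wilcoxon rank-sum test. The
#' exact null distribution is used when both groups have at most 12 members
#' and the coordinates are tie-free; otherwise the normal approximation with
#' tie correction.
#'
#' @param emb an [classical_mds()] embedding of exemplars.
#' @param category_labels category of each embedded exemplar (row of the
#'   coordinate matrix).
#' @param dims dimensions to test (default the first 4 available).
#' @return data frame with columns `category_a`, `category_b`, `dimension`,
#'   `p_value`; one row per pair x dimension.
#' @export
ranksum_separability <- function(emb, category_labels,
                                 dims = seq_len(min(4L, ncol(emb$coordinates)))) {
  stopifnot(inherits(emb, "mds_embedding"))
  category_labels <- as.vector(category_labels)
  if (length(category_labels) != nrow(emb$coordinates))
    stop("one category label per embedded point required")
  cats <- sort(unique(category_labels))
  if (any(table(category_labels) < 2L))
    stop("every category needs at least 2 exemplars")
  pairs <- utils::combn(cats, 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(pi) {
    a <- pairs[1L, pi]; b <- pairs[2L, pi]
    do.call(rbind, lapply(dims, function(dim) {
      xa <- emb$coordinates[category_labels == a, dim]
      xb <- emb$coordinates[category_labels == b, dim]
      exact <- length(xa) <= 12L && length(xb) <= 12L
      p <- suppressWarnings(
        stats::wilcox.test(xa, xb, alternative = "two.sided",
                           exact = exact, correct = TRUE)$p.value)
      data.frame(category_a = a, category_b = b, dimension = dim,
                 p_value = p)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Bundle decoding statistics into a report
#'
#' @param result a [crossvalidate()] result.
#' @param alpha significance level for the accompanying threshold.
#' @return list with accuracy, exact binomial `p`, effect size `d`, per-fold
#'   counts and the significance threshold, suitable for JSON export.
#' @export
classification_report <- function(result, alpha = 0.01) {
  stopifnot(inherits(result, "decoding_result"))
  n <- sum(result$confusion$counts)
  chance <- 1 / length(result$confusion$classes)
  rep <- binomial_pvalue(sum(result$fold_correct), n, result$n_folds, chance)
  list(level = result$level,
       n_classes = length(result$confusion$classes),
       n_trials = n,
       accuracy = rep$accuracy,
       chance = chance,
       p = rep$p_value,
       d = rep$d,
       n_fold = rep$n_fold,
       c_fold = rep$c_fold,
       threshold_at_alpha = significance_threshold(n, result$n_folds,
                                                   chance, alpha),
       alpha = alpha,
       fold_k = result$fold_k,
       fold_correct = result$fold_correct)
}
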