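#' Self-normalize a row-stochastic confusion matrix
#'
#' Divides every entry by the diagonal of its row, `CM_ij / CM_ii`, so each
#' class has unit self-similarity. This is the step that lets a multi-class
#' confusion matrix — whose diagonal carries per-class discriminability,
#' unlike pairwise-correlation or pairwise-classification dissimilarities —
#' be converted into a similarity space.
#'
#' @param CM square numeric matrix (row-stochastic confusion proportions) or
#'   a [confusion_matrix()] object, whose `normalized` slot is used.
#' @return square matrix with unit diagonal.
#' @export
self_normalize <- function(CM) {
  if (inherits(CM, "confusion_matrix")) CM <- CM$normalized
  CM <- as.matrix(CM)
  if (nrow(CM) != ncol(CM)) stop("confusion matrix must be square")
  d <- diag(CM)
  if (any(d <= 0)) {
    bad <- which(d <= 0)
    stop("zero diagonal for class(es) ", paste(rownames(CM)[bad] %||% bad,
         collapse = ", "), ": self-normalization undefined; ",
         "merge or drop these classes")
  }
  CM / d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Symmetrize a self-normalized confusion matrix
#'
#' Elementwise geometric mean of the matrix and its transpose,
#' `S_ij = sqrt(CM'_ij * CM'_ji)`, yielding a symmetric similarity matrix
#' with unit diagonal.
#'
#' @param CMp self-normalized confusion matrix (unit diagonal, nonnegative).
#' @return symmetric similarity matrix `S`.
#' @export
symmetrize_similarity <- function(CMp) {
  CMp <- as.matrix(CMp)
  if (any(CMp < 0)) stop("negative entries in self-normalized confusion matrix")
  if (max(abs(diag(CMp) - 1)) > 1e-8)
    stop("self-normalized confusion matrix must have unit diagonal")
  sqrt(CMp * t(CMp))
}

#' Extract the representational distance vector from a similarity matrix
#'
#' `D = L(1 - S)`: the lower triangle of `1 - S`, vectorized in the condensed
#' order (column by column, rows below the diagonal — the order used by
#' [stats::dist]). Similarities above 1 (possible when an off-diagonal
#' confusion exceeds its row diagonal) would give negative distances; these
#' are clipped to 0 and flagged.
#'
#' @param S symmetric similarity matrix with unit diagonal.
#' @return An object of class `similarity_space`: `S`, `D` (a [stats::dist]
#'   condensed distance vector of length N(N-1)/2), `clipped` flag, and
#'   `classes`.
#' @export
to_distance <- function(S) {
  S <- as.matrix(S)
  if (max(abs(S - t(S))) > 1e-8) stop("similarity matrix must be symmetric")
  D <- 1 - S
  clipped <- any(D[lower.tri(D)] < 0)
  D[D < 0] <- 0
  d <- stats::as.dist(D)
  structure(list(S = S, D = d, clipped = clipped,
                 classes = rownames(S) %||% seq_len(nrow(S))),
            class = "similarity_space")
}

#' Full confusion-matrix to RDM chain
#'
#' Convenience composition of [self_normalize()], [symmetrize_similarity()]
#' and [to_distance()]: the route from a normalized multi-class confusion
#' matrix to the condensed representational dissimilarity vector used for
#' multidimensional scaling and clustering.
#'
#' @inheritParams self_normalize
#' @return A `similarity_space` (see [to_distance()]).
#' @export
confusion_to_distance <- function(CM) {
  to_distance(symmetrize_similarity(self_normalize(CM)))
}

#' @export
print.similarity_space <- function(x, ...) {
  cat(sprintf("Similarity space over %d classes; %d pairwise distances%s\n",
              nrow(x$S), length(x$D),
              if (x$clipped) " (some distances clipped at 0)" else ""))
  invisible(x)
}
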