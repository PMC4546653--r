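#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a condensed distance vector in Euclidean coordinates: the squared
#' distance matrix is double-centered, `B = -1/2 J D^2 J`, and
#' eigendecomposed; coordinates are eigenvectors scaled by the square roots
#' of the eigenvalues. Only eigenvalues exceeding `tol` times the largest are
#' kept, so non-Euclidean distance sets simply lose their negative (and
#' near-zero) directions. Dimensions are ordered by descending eigenvalue —
#' dimension 1 explains the most variance — and each dimension's sign is
#' fixed so its largest-magnitude coordinate is positive.
#'
#' @param D a [stats::dist] object or `similarity_space`, or a square
#'   symmetric distance matrix.
#' @param tol relative eigenvalue tolerance (default 1e-10).
#' @return An object of class `mds_embedding`: `coordinates` (N x m),
#'   `eigenvalues` (length m, decreasing, positive), `n_negative` (count of
#'   negative eigenvalues dropped), `classes`.
#' @export
classical_mds <- function(D, tol = 1e-10) {
  classes <- NULL
  if (inherits(D, "similarity_space")) { classes <- D$classes; D <- D$D }
  Dm <- as.matrix(D)
  if (is.null(classes)) classes <- rownames(Dm) %||% seq_len(nrow(Dm))
  n <- nrow(Dm)
  if (any(Dm < 0)) stop("distances must be nonnegative")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (Dm^2) %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- eg$values > tol * max(eg$values, 0)
  if (!any(keep)) {
    return(structure(list(coordinates = matrix(0, n, 0),
                          eigenvalues = numeric(0),
                          n_negative = sum(eg$values < 0),
                          classes = classes), class = "mds_embedding"))
  }
  vals <- eg$values[keep]
  vecs <- eg$vectors[, keep, drop = FALSE]
  coords <- sweep(vecs, 2L, sqrt(vals), `*`)
  for (j in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, j])), j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- classes
  structure(list(coordinates = coords, eigenvalues = vals,
                 n_negative = sum(eg$values < 0), classes = classes),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("Classical MDS embedding: %d points in %d dimensions\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  if (length(x$eigenvalues))
    cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = " "), "\n")
  invisible(x)
}

#' UPGMA hierarchical clustering of a distance vector
#'
#' Average-linkage agglomeration in the unweighted (group-average) sense: at
#' each step the pair of clusters with the smallest mean inter-member
#' distance is merged, at a height equal to that mean distance. Ties are
#' broken toward the lexicographically smallest pair of lowest original leaf
#' indices, so the tree is deterministic. Heights are nondecreasing and the
#' implied cophenetic distances are ultrametric.
#'
#' @param D a [stats::dist], `similarity_space`, or square symmetric distance
#'   matrix over at least two items.
#' @return An object of class `upgma_dendrogram`: `merge` and `height` in
#'   [stats::hclust] conventions, `leaf_order` for display, `labels`, and an
#'   `hclust` member holding the equivalent `hclust` object.
#' @export
upgma <- function(D) {
  labels <- NULL
  if (inherits(D, "similarity_space")) { labels <- as.character(D$classes); D <- D$D }
  Dm <- as.matrix(D)
  n <- nrow(Dm)
  if (n < 2L) stop("need at least 2 items to cluster")
  if (is.null(labels)) labels <- rownames(Dm) %||% as.character(seq_len(n))
  # active clusters: list of member leaf indices; id <0 = leaf, >0 = merge row
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)
  minleaf <- seq_len(n)            # smallest original leaf index per cluster
  d <- Dm
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(members)
    best <- c(Inf, 0L, 0L)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      dij <- d[i, j]
      better <- dij < best[1L] - 1e-12
      tie <- abs(dij - best[1L]) <= 1e-12
      if (better || (tie && !identical(best[2L], 0) &&
                     tie_before(minleaf[i], minleaf[j],
                                minleaf[best[2L]], minleaf[best[3L]])))
        best <- c(dij, i, j)
    }
    i <- best[2L]; j <- best[3L]
    height[step] <- best[1L]
    merge[step, ] <- sort_merge_pair(ids[i], ids[j], minleaf[i], minleaf[j])
    ni <- length(members[[i]]); nj <- length(members[[j]])
    # unweighted group average: size-weighted combination of distances
    newd <- (ni * d[i, ] + nj * d[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
    minleaf <- c(minleaf[keep], min(minleaf[i], minleaf[j]))
    ids <- c(ids[keep], step)
  }
  hc <- structure(list(merge = merge, height = height,
                       order = hclust_order(merge),
                       labels = labels, method = "average",
                       call = match.call(), dist.method = "user"),
                  class = "hclust")
  structure(list(merge = merge, height = height,
                 leaf_order = hc$order, labels = labels, hclust = hc),
            class = "upgma_dendrogram")
}

# lexicographic comparison of merge pairs by (min leaf of the pair, max leaf)
tie_before <- function(a1, a2, b1, b2) {
  pa <- sort(c(a1, a2)); pb <- sort(c(b1, b2))
  pa[1L] < pb[1L] || (pa[1L] == pb[1L] && pa[2L] < pb[2L])
}

# hclust convention: the cluster containing the smaller original leaf first
sort_merge_pair <- function(ida, idb, mina, minb) {
  if (mina <= minb) c(ida, idb) else c(idb, ida)
}

# leaf display order by in-order traversal of the merge tree
hclust_order <- function(merge) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram over %d leaves; merge heights %s\n",
              length(x$labels),
              paste(signif(x$height, 4), collapse = " ")))
  invisible(x)
}

#' Cophenetic distances of a UPGMA dendrogram
#'
#' @param dend an [upgma()] result.
#' @return a [stats::dist] of cophenetic distances (merge heights at which
#'   pairs first join); ultrametric by construction.
#' @export
cophenetic_distances <- function(dend) {
  stopifnot(inherits(dend, "upgma_dendrogram"))
  stats::cophenetic(dend$hclust)
}

#' Cut a dendrogram at the top into two groups
#'
#' The "top cut": membership of the two clusters merged at the final (highest)
#' merge, e.g. to compare against a planted superordinate split.
#'
#' @param dend an [upgma()] result.
#' @return integer vector of group assignments (1/2) per leaf.
#' @export
top_cut <- function(dend) {
  stopifnot(inherits(dend, "upgma_dendrogram"))
  stats::cutree(dend$hclust, k = 2L)
}

#' Export a dendrogram to Newick
#'
#' @param dend an [upgma()] result.
#' @param path optional file path; when given, writes the tree and returns
#'   the path, otherwise returns the Newick string.
#' @return Newick string or `path`, invisibly when written.
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  stopifnot(inherits(dend, "upgma_dendrogram"))
  phy <- ape::as.phylo(dend$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Reorder a confusion matrix to match a dendrogram's leaf order
#'
#' Permutes rows and columns of the (count or normalized) confusion matrix by
#' the dendrogram's display leaf order, so that clustered classes are
#' adjacent and block structure becomes visible. Contents are untouched.
#'
#' @param CM a [confusion_matrix()] or a square matrix whose rows/columns are
#'   in the dendrogram's original class order.
#' @param dend an [upgma()] result over the same classes.
#' @return object of the same type as `CM`, permuted.
#' @export
reorder_confusion <- function(CM, dend) {
  stopifnot(inherits(dend, "upgma_dendrogram"))
  ord <- dend$leaf_order
  if (inherits(CM, "confusion_matrix")) {
    if (length(CM$classes) != length(dend$labels))
      stop("confusion matrix classes do not match dendrogram leaves")
    return(confusion_matrix(CM$counts[ord, ord, drop = FALSE],
                            CM$classes[ord]))
  }
  CM <- as.matrix(CM)
  if (nrow(CM) != length(dend$labels))
    stop("confusion matrix classes do not match dendrogram leaves")
  CM[ord, ord, drop = FALSE]
}
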