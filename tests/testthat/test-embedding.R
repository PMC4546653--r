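test_that("classical MDS reproduces Euclidean configurations", {
  # equilateral triangle: all recovered distances 1, two positive eigenvalues
  D3 <- matrix(1, 3, 3); diag(D3) <- 0
  emb <- classical_mds(as.dist(D3))
  expect_equal(length(emb$eigenvalues), 2)
  expect_equal(as.vector(dist(emb$coordinates)), rep(1, 3), tolerance = 1e-9)

  # planted coordinates round-trip up to rotation/reflection
  set.seed(8)
  X <- matrix(rnorm(7 * 3), 7, 3)
  emb2 <- classical_mds(dist(X))
  expect_equal(as.vector(dist(emb2$coordinates)), as.vector(dist(X)),
               tolerance = 1e-9)
  # dimensions ordered by descending eigenvalue, all positive
  expect_true(all(diff(emb2$eigenvalues) <= 1e-12))
  expect_true(all(emb2$eigenvalues > 0))
  # eigenvalue conservation: kept eigenvalues sum to the total dispersion
  Dm <- as.matrix(dist(X))
  J <- diag(7) - matrix(1 / 7, 7, 7)
  expect_equal(sum(emb2$eigenvalues), sum(diag(-0.5 * J %*% Dm^2 %*% J)),
               tolerance = 1e-9)
  # deterministic sign convention
  expect_identical(emb2$coordinates, classical_mds(dist(X))$coordinates)

  # agreement with the reference implementation in base R
  ref <- cmdscale(dist(X), k = 3)
  expect_equal(abs(emb2$coordinates), abs(ref), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("non-Euclidean distances lose their negative directions", {
  # violates the triangle inequality: d(1,3) > d(1,2) + d(2,3)
  Dm <- matrix(c(0, 1, 5, 1, 0, 1, 5, 1, 0), 3, 3)
  emb <- classical_mds(as.dist(Dm))
  expect_gt(emb$n_negative, 0)
  expect_true(all(emb$eigenvalues > 0))
  # degenerate all-zero distances: single-point embedding, no exception
  expect_equal(ncol(classical_mds(as.dist(matrix(0, 3, 3)))$coordinates), 0)
})

test_that("UPGMA reproduces the hand-computed average-linkage merge", {
  # d(A,B) = 0.2, d(A,C) = 0.6, d(B,C) = 0.8:
  # merge (A,B) at 0.2, then C joins at (0.6 + 0.8) / 2 = 0.7
  Dm <- matrix(0, 3, 3)
  Dm[1, 2] <- Dm[2, 1] <- 0.2
  Dm[1, 3] <- Dm[3, 1] <- 0.6
  Dm[2, 3] <- Dm[3, 2] <- 0.8
  dend <- upgma(as.dist(Dm))
  expect_equal(dend$height, c(0.2, 0.7))
  expect_equal(dend$merge[1, ], c(-1L, -2L))

  # all distances equal: tie rule merges leaves 1 and 2 first, equal heights
  De <- matrix(0.4, 4, 4); diag(De) <- 0
  dte <- upgma(as.dist(De))
  expect_equal(dte$merge[1, ], c(-1L, -2L))
  expect_equal(dte$height, rep(0.4, 3))

  expect_error(upgma(as.dist(matrix(0, 1, 1))), "at least 2")
})

test_that("UPGMA matches the brute-force average-linkage oracle", {
  set.seed(17)
  for (rep in 1:100) {
    N <- sample(3:8, 1)
    Dm <- as.matrix(dist(matrix(rnorm(N * 2), N, 2)))
    dend <- upgma(as.dist(Dm))
    oracle <- oracle_upgma(Dm)
    expect_equal(dend$height, oracle$heights, tolerance = 1e-10)
    expect_equal(as.matrix(cophenetic_distances(dend)),
                 oracle$cophenetic, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("UPGMA heights are nondecreasing and cophenetic distances ultrametric", {
  set.seed(18)
  for (rep in 1:20) {
    N <- sample(4:9, 1)
    Dm <- matrix(runif(N * N), N, N); Dm <- (Dm + t(Dm)) / 2; diag(Dm) <- 0
    dend <- upgma(as.dist(Dm))
    expect_true(all(diff(dend$height) >= -1e-12))
    C <- as.matrix(cophenetic_distances(dend))
    for (i in 1:(N - 2)) for (j in (i + 1):(N - 1)) for (k in (j + 1):N)
      expect_lte(C[i, j], max(C[i, k], C[j, k]) + 1e-12)
  }
})

test_that("UPGMA agrees with hclust average linkage on tie-free instances", {
  set.seed(19)
  d <- dist(matrix(rnorm(20), 10, 2))
  dend <- upgma(d)
  hc <- hclust(d, method = "average")
  expect_equal(dend$height, hc$height, tolerance = 1e-10)
  expect_equal(as.matrix(cophenetic_distances(dend)),
               as.matrix(cophenetic(hc)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("Newick export round-trips through ape", {
  d <- dist(matrix(rnorm(12), 6, 2))
  dend <- upgma(d)
  txt <- dendrogram_newick(dend)
  phy <- ape::read.tree(text = txt)
  expect_equal(sort(phy$tip.label), sort(dend$labels))
  path <- withr::local_tempfile(fileext = ".newick")
  dendrogram_newick(dend, path)
  expect_true(file.exists(path))
})

test_that("confusion reordering permutes by leaf order and is an involution", {
  set.seed(20)
  # block-structured confusion with scrambled class order
  n <- 6
  blocks <- c(1, 2, 1, 2, 1, 2)  # interleaved two-block structure
  raw <- matrix(2, n, n)
  raw[outer(blocks, blocks, "==")] <- 20
  diag(raw) <- 40
  cm <- confusion_matrix(raw)
  dend <- upgma(confusion_to_distance(cm))
  reord <- reorder_confusion(cm, dend)
  # after reordering, each block's classes are contiguous
  ord_blocks <- blocks[dend$leaf_order]
  expect_equal(length(rle(ord_blocks)$lengths), 2)
  # contents untouched, just permuted
  expect_equal(sort(as.vector(reord$counts)), sort(as.vector(cm$counts)))

  # identity permutation leaves the matrix unchanged (all-tie tree has
  # leaf order 1..N under the lexicographic tie rule)
  m <- matrix(1:16, 4, 4)
  dident <- upgma(as.dist(matrix(c(0, 1, 1, 1, 1, 0, 1, 1, 1, 1, 0, 1,
                                   1, 1, 1, 0), 4, 4)))
  expect_equal(dident$leaf_order, 1:4)
  expect_equal(reorder_confusion(m, dident), m)
  # a reversal permutation applied twice restores the matrix
  drev <- dident
  drev$leaf_order <- 4:1
  expect_equal(reorder_confusion(reorder_confusion(m, drev), drev), m)
  expect_error(reorder_confusion(matrix(0, 3, 3), dident), "match")
})
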