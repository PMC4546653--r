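test_that("reshaping concatenates electrode time courses in electrode-major order", {
  # 2x2 epoch [[a,b],[c,d]] -> row (a,b,c,d)
  ep <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  ds <- reshape_spacetime_to_trialspace(list(ep), exemplar_labels = 1,
                                        category_labels = 1)
  expect_equal(as.vector(ds$X1), c(1, 2, 3, 4))

  # the deposited-data geometry: 124 electrodes x 32 samples -> 3,968 columns
  ep_big <- matrix(rnorm(124 * 32), 124, 32)
  ds_big <- reshape_spacetime_to_trialspace(list(ep_big), 1, 1)
  expect_equal(ncol(ds_big$X1), 3968)

  # single electrode: trial-space rows are the time courses unchanged
  eps <- lapply(1:3, function(i) matrix(rnorm(8), 1, 8))
  ds1 <- reshape_spacetime_to_trialspace(eps, 1:3, c(1, 1, 2))
  expect_equal(ds1$X1, do.call(rbind, eps), ignore_attr = TRUE)

  expect_error(reshape_spacetime_to_trialspace(
    list(matrix(0, 2, 3), matrix(0, 2, 4)), 1:2, c(1, 1)), "ragged")
})

test_that("reshape followed by unreshape recovers the epochs exactly", {
  set.seed(5)
  eps <- lapply(1:6, function(i) matrix(rnorm(5 * 7), 5, 7))
  ds <- reshape_spacetime_to_trialspace(eps, rep(1:3, 2), rep(1, 6))
  back <- trialspace_to_spacetime(ds)
  expect_equal(back, eps)
})

test_that("feature selection follows the electrode-major column bookkeeping", {
  set.seed(9)
  ne <- 5; nt <- 8
  eps <- lapply(1:4, function(i) matrix(rnorm(ne * nt), ne, nt))
  ds <- reshape_spacetime_to_trialspace(eps, 1:4, rep(1, 4))

  # brute-force index enumeration oracle for several selectors
  cases <- list(list(e = 3L, s = 0L, st = nt),
                list(e = c(2L, 5L), s = 2L, st = 6L),
                list(e = 1:ne, s = 1L, st = 7L))
  for (cs in cases) {
    sub <- select_features(ds, feature_selector(cs$e, cs$s, cs$st))
    expected <- do.call(rbind, lapply(eps, function(ep) {
      as.vector(t(ep[cs$e, (cs$s + 1):cs$st, drop = FALSE]))
    }))
    expect_equal(sub$X1, expected, ignore_attr = TRUE)
    expect_equal(ncol(sub$X1), length(cs$e) * (cs$st - cs$s))
    # bijection of (electrode, sample) onto the output columns
    cols <- feature_columns(cs$e, cs$s:(cs$st - 1L), nt)
    expect_equal(sort(unique(cols)), sort(cols))
  }

  # one electrode, full 32-sample window has K = 32 columns
  ds32 <- reshape_spacetime_to_trialspace(
    lapply(1:2, function(i) matrix(rnorm(3 * 32), 3, 32)), 1:2, c(1, 1))
  expect_equal(ncol(select_features(ds32, feature_selector(2, 0, 32))$X1), 32)

  # all electrodes with a 6-sample window: K = n_electrodes * 6
  expect_equal(ncol(select_features(ds32, feature_selector(1:3, 9, 15))$X1), 18)

  # full selector is the identity
  full <- select_features(ds, feature_selector(1:ne, 0, nt))
  expect_identical(full$X1, ds$X1)

  expect_error(feature_selector(integer(0), 0, 4), "empty")
  expect_error(select_features(ds, feature_selector(9, 0, 4)), "bounds")
})

test_that("feature selection commutes with trial-row permutation", {
  set.seed(3)
  eps <- lapply(1:6, function(i) matrix(rnorm(4 * 6), 4, 6))
  ds <- reshape_spacetime_to_trialspace(eps, rep(1:3, 2), rep(1, 6))
  sel <- feature_selector(c(1L, 4L), 1L, 5L)
  perm <- sample(6)
  ds_perm <- trialspace_dataset(ds$X1[perm, ], ds$exemplar_labels[perm],
                                ds$category_labels[perm], 4, 6)
  expect_equal(select_features(ds_perm, sel)$X1,
               select_features(ds, sel)$X1[perm, ])
})

test_that("dataset save/load round-trips and validates its fields", {
  ds <- make_separable_ds(5)

  rds <- withr::local_tempfile(fileext = ".rds")
  save_dataset(ds, rds)
  expect_identical(load_dataset(rds)$X1, ds$X1)
  expect_identical(load_dataset(rds)$exemplar_labels, ds$exemplar_labels)

  csv <- withr::local_tempfile(fileext = ".csv")
  save_dataset(ds, csv)
  back <- load_dataset(csv)
  expect_equal(back$X1, ds$X1, tolerance = 1e-12)
  expect_identical(back$category_labels, ds$category_labels)
  expect_identical(back$n_electrodes, ds$n_electrodes)

  # label/matrix length mismatch is a format error naming the field
  expect_error(trialspace_dataset(matrix(0, 6, 4), exemplar_labels = 1:5,
                                  category_labels = rep(1, 6),
                                  n_electrodes = 2, n_time_samples = 2),
               "exemplar")
})

test_that("foreign list containers are read through a key map", {
  set.seed(2)
  X <- matrix(rnorm(12), 6, 2)
  path <- withr::local_tempfile(fileext = ".rds")
  # container with exemplar labels and an exemplar->category map, but no
  # per-trial category labels: categories must be derived by composition
  saveRDS(list(data = X, img = c(1, 1, 2, 2, 3, 3), img2cat = c(1, 1, 2)),
          path)
  ds <- load_dataset(path, keymap = list(X1 = "data", exemplar = "img",
                                         exemplar_to_category = "img2cat"))
  expect_equal(ds$category_labels, c(1L, 1L, 1L, 1L, 2L, 2L))

  saveRDS(list(img = 1:6), path)
  expect_error(load_dataset(path, keymap = list(exemplar = "img")), "X1")
})
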