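#' Construct a trial-space EEG dataset
#'
#' A trial-space dataset holds one row per experimental trial. Each row is the
#' electrode-major concatenation of that trial's epoch: electrode \code{e}'s
#' full time course occupies the contiguous columns
#' \code{(e-1)*nTimeSamples + 1 : e*nTimeSamples}. This is the layout produced
#' by reshaping a stack of space-time epoch matrices (electrodes x samples)
#' with [reshape_spacetime_to_trialspace()].
#'
#' @param X1 numeric matrix, trials x features (voltage, arbitrary units).
#' @param exemplar_labels integer vector, one exemplar (image) label per trial.
#' @param category_labels integer vector, one category label per trial. May be
#'   omitted when `exemplar_to_category` is given, in which case categories are
#'   derived by composition.
#' @param n_electrodes,n_time_samples epoch geometry; their product must equal
#'   `ncol(X1)`.
#' @param sampling_rate_hz sampling rate of the epoch samples (default 62.5,
#'   i.e. a 16 ms sample period).
#' @param epoch_start_ms time of sample 1 relative to stimulus onset.
#' @param exemplar_to_category optional integer vector mapping exemplar index
#'   to category index (position = exemplar).
#' @return An object of class `trialspace_dataset`.
#' @seealso [select_features()], [simulate_dataset()]
#' @export
trialspace_dataset <- function(X1, exemplar_labels, category_labels = NULL,
                               n_electrodes, n_time_samples,
                               sampling_rate_hz = 62.5, epoch_start_ms = 0,
                               exemplar_to_category = NULL) {
  X1 <- as.matrix(X1)
  if (!is.numeric(X1)) stop("X1 must be a numeric matrix")
  n_electrodes <- as.integer(n_electrodes)
  n_time_samples <- as.integer(n_time_samples)
  if (n_electrodes < 1L || n_time_samples < 1L)
    stop("n_electrodes and n_time_samples must be >= 1")
  if (ncol(X1) != n_electrodes * n_time_samples)
    stop(sprintf("ncol(X1) = %d but n_electrodes * n_time_samples = %d",
                 ncol(X1), n_electrodes * n_time_samples))
  exemplar_labels <- as.integer(exemplar_labels)
  if (length(exemplar_labels) != nrow(X1))
    stop(sprintf("exemplar_labels has length %d for %d trials (field: exemplar)",
                 length(exemplar_labels), nrow(X1)))
  if (is.null(category_labels)) {
    if (is.null(exemplar_to_category))
      stop("category_labels missing and no exemplar_to_category map given (field: category)")
    category_labels <- as.integer(exemplar_to_category[exemplar_labels])
    if (anyNA(category_labels))
      stop("exemplar_to_category map does not cover all exemplar labels (field: category)")
  }
  category_labels <- as.integer(category_labels)
  if (length(category_labels) != nrow(X1))
    stop(sprintf("category_labels has length %d for %d trials (field: category)",
                 length(category_labels), nrow(X1)))
  # exemplar -> category must be a function
  map <- unique(cbind(exemplar_labels, category_labels))
  if (anyDuplicated(map[, 1L]))
    stop("an exemplar maps to more than one category (field: exemplar/category)")
  structure(list(
    X1 = X1,
    exemplar_labels = exemplar_labels,
    category_labels = category_labels,
    n_electrodes = n_electrodes,
    n_time_samples = n_time_samples,
    sampling_rate_hz = sampling_rate_hz,
    epoch_start_ms = epoch_start_ms
  ), class = "trialspace_dataset")
}

#' @export
print.trialspace_dataset <- function(x, ...) {
  cat(sprintf(paste0(
    "Trial-space EEG dataset: %d trials x %d features\n",
    "  %d electrodes x %d samples at %g Hz (electrode-major feature order)\n",
    "  %d exemplars in %d categories\n"),
    nrow(x$X1), ncol(x$X1), x$n_electrodes, x$n_time_samples,
    x$sampling_rate_hz, length(unique(x$exemplar_labels)),
    length(unique(x$category_labels))))
  invisible(x)
}

#' Reshape space-time epochs to a trial-space matrix
#'
#' Each epoch is an electrodes x samples matrix; its trial-space row is the
#' concatenation of the electrode time courses in electrode order, so the full
#' time course of one electrode occupies contiguous columns.
#'
#' @param epochs a list of equally sized numeric matrices (electrodes x
#'   samples), or a 3-d array with dimensions electrodes x samples x trials.
#' @inheritParams trialspace_dataset
#' @param exemplar_labels,category_labels,exemplar_to_category trial labels,
#'   passed through to [trialspace_dataset()].
#' @return A `trialspace_dataset`.
#' @export
reshape_spacetime_to_trialspace <- function(epochs, exemplar_labels,
                                            category_labels = NULL,
                                            sampling_rate_hz = 62.5,
                                            epoch_start_ms = 0,
                                            exemplar_to_category = NULL) {
  if (is.array(epochs) && length(dim(epochs)) == 3L) {
    epochs <- lapply(seq_len(dim(epochs)[3L]), function(t) epochs[, , t])
  }
  if (!is.list(epochs) || length(epochs) == 0L)
    stop("epochs must be a non-empty list of matrices or a 3-d array")
  dims <- vapply(epochs, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("ragged epoch stack: all epochs must share electrode and sample counts")
  ne <- dims[1L, 1L]; nt <- dims[2L, 1L]
  # row-major flatten of each epoch = electrode-major feature order
  X1 <- t(vapply(epochs, function(m) as.vector(t(m)), numeric(ne * nt)))
  trialspace_dataset(X1, exemplar_labels, category_labels,
                     n_electrodes = ne, n_time_samples = nt,
                     sampling_rate_hz = sampling_rate_hz,
                     epoch_start_ms = epoch_start_ms,
                     exemplar_to_category = exemplar_to_category)
}

#' Recover space-time epochs from a trial-space dataset
#'
#' Inverse of [reshape_spacetime_to_trialspace()]: returns the list of
#' electrodes x samples epoch matrices, exactly as they were before reshaping.
#'
#' @param ds a `trialspace_dataset`.
#' @return list of numeric matrices, one per trial.
#' @export
trialspace_to_spacetime <- function(ds) {
  stopifnot(inherits(ds, "trialspace_dataset"))
  lapply(seq_len(nrow(ds$X1)), function(t) {
    matrix(ds$X1[t, ], nrow = ds$n_electrodes, ncol = ds$n_time_samples,
           byrow = TRUE)
  })
}

#' Feature selector for searchlight subsetting
#'
#' Describes a spatial/temporal subset of the feature columns: an ordered set
#' of electrodes and a half-open window `[start, stop)` of 0-based sample
#' indices.
#'
#' @param electrodes integer vector of electrode indices (1-based).
#' @param sample_start,sample_stop half-open sample window, 0-based
#'   (`sample_start = 0, sample_stop = n_time_samples` selects the full epoch).
#' @return An object of class `feature_selector`.
#' @export
feature_selector <- function(electrodes, sample_start, sample_stop) {
  electrodes <- as.integer(electrodes)
  if (length(electrodes) == 0L) stop("empty electrode selection")
  if (anyDuplicated(electrodes)) stop("duplicate electrodes in selection")
  sample_start <- as.integer(sample_start)
  sample_stop <- as.integer(sample_stop)
  if (sample_stop <= sample_start) stop("empty sample window")
  structure(list(electrodes = electrodes, sample_start = sample_start,
                 sample_stop = sample_stop), class = "feature_selector")
}

#' Map (electrode, sample) pairs to trial-space column indices
#'
#' @param electrodes electrode indices (1-based).
#' @param samples 0-based sample indices within the epoch.
#' @param n_time_samples samples per epoch.
#' @return integer vector of column indices, electrode-major: all requested
#'   samples of the first electrode, then the second, and so on.
#' @export
feature_columns <- function(electrodes, samples, n_time_samples) {
  as.integer(outer(samples + 1L, (electrodes - 1L) * n_time_samples, `+`))
}

#' Subset a dataset's features by electrodes and sample window
#'
#' Returns a new dataset whose feature matrix holds only the selected
#' electrodes' selected samples, preserving the electrode-major convention and
#' all trial labels. Used by the searchlight analyses to restrict the feature
#' vector to one electrode and/or one temporal window.
#'
#' @param ds a `trialspace_dataset`.
#' @param sel a [feature_selector()].
#' @return A `trialspace_dataset` with `K = length(electrodes) * window length`
#'   feature columns.
#' @export
select_features <- function(ds, sel) {
  stopifnot(inherits(ds, "trialspace_dataset"), inherits(sel, "feature_selector"))
  if (any(sel$electrodes < 1L) || any(sel$electrodes > ds$n_electrodes))
    stop("electrode selection out of bounds")
  if (sel$sample_start < 0L || sel$sample_stop > ds$n_time_samples)
    stop("sample window out of bounds")
  samples <- seq.int(sel$sample_start, sel$sample_stop - 1L)
  cols <- feature_columns(sel$electrodes, samples, ds$n_time_samples)
  trialspace_dataset(ds$X1[, cols, drop = FALSE],
                     ds$exemplar_labels, ds$category_labels,
                     n_electrodes = length(sel$electrodes),
                     n_time_samples = length(samples),
                     sampling_rate_hz = ds$sampling_rate_hz,
                     epoch_start_ms = ds$epoch_start_ms +
                       sel$sample_start * 1000 / ds$sampling_rate_hz)
}

#' Keep only trials belonging to selected classes
#'
#' @param ds a `trialspace_dataset`.
#' @param categories,exemplars keep trials whose category (resp. exemplar)
#'   label is in the given set; give exactly one of the two.
#' @return A `trialspace_dataset` restricted to the matching trials.
#' @export
subset_trials <- function(ds, categories = NULL, exemplars = NULL) {
  stopifnot(inherits(ds, "trialspace_dataset"))
  if (is.null(categories) == is.null(exemplars))
    stop("give exactly one of categories or exemplars")
  keep <- if (!is.null(categories)) ds$category_labels %in% categories
          else ds$exemplar_labels %in% exemplars
  if (!any(keep)) stop("no trials match the requested classes")
  trialspace_dataset(ds$X1[keep, , drop = FALSE],
                     ds$exemplar_labels[keep], ds$category_labels[keep],
                     n_electrodes = ds$n_electrodes,
                     n_time_samples = ds$n_time_samples,
                     sampling_rate_hz = ds$sampling_rate_hz,
                     epoch_start_ms = ds$epoch_start_ms)
}

#' Save / load trial-space datasets
#'
#' Two container formats are supported, chosen by file extension:
#' \describe{
#'   \item{`.rds`}{the package's native container; a save/load round trip is
#'     bit-identical for the matrix and labels.}
#'   \item{`.csv`}{a plain-text export for small fixtures: one row per trial,
#'     columns `exemplar`, `category`, then feature columns `f1..fK`; epoch
#'     geometry is stored in a `<path>.meta.json` sidecar.}
#' }
#' `load_dataset()` additionally accepts `.rds` files holding a plain named
#' list (a matrix plus label vectors, as exported from other toolboxes); the
#' `keymap` argument names which list entries hold which fields, defaulting to
#' `X1`/`exemplar`/`category`. A missing `category` entry is tolerated when
#' the list carries an `exemplar_to_category` map (under the keymap's
#' `exemplar_to_category` name), from which categories are derived.
#'
#' @param ds a `trialspace_dataset`.
#' @param path file path ending in `.rds` or `.csv`.
#' @param keymap named list mapping the fields `X1`, `exemplar`, `category`,
#'   `n_electrodes`, `n_time_samples`, `exemplar_to_category` to the key names
#'   used inside a foreign list container.
#' @return `load_dataset()` returns a `trialspace_dataset`; `save_dataset()`
#'   returns `path` invisibly.
#' @export
save_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "trialspace_dataset"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    saveRDS(ds, path)
  } else if (ext == "csv") {
    df <- data.frame(exemplar = ds$exemplar_labels,
                     category = ds$category_labels, ds$X1)
    names(df)[-(1:2)] <- paste0("f", seq_len(ncol(ds$X1)))
    utils::write.csv(df, path, row.names = FALSE)
    meta <- list(n_electrodes = ds$n_electrodes,
                 n_time_samples = ds$n_time_samples,
                 sampling_rate_hz = ds$sampling_rate_hz,
                 epoch_start_ms = ds$epoch_start_ms)
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  } else stop("unsupported dataset extension: ", ext)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path, keymap = list()) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    obj <- readRDS(path)
    if (inherits(obj, "trialspace_dataset")) return(validate_loaded(obj))
    if (!is.list(obj)) stop("rds file does not hold a dataset or list container")
    km <- utils::modifyList(list(
      X1 = "X1", exemplar = "exemplar", category = "category",
      n_electrodes = "n_electrodes", n_time_samples = "n_time_samples",
      exemplar_to_category = "exemplar_to_category"), keymap)
    X1 <- obj[[km$X1]]
    if (is.null(X1)) stop("container missing matrix key '", km$X1, "' (field: X1)")
    ex <- obj[[km$exemplar]]
    if (is.null(ex)) stop("container missing key '", km$exemplar, "' (field: exemplar)")
    ne <- obj[[km$n_electrodes]]
    nt <- obj[[km$n_time_samples]]
    if (is.null(ne) || is.null(nt)) {
      # fall back to single-electrode geometry when the container has none
      ne <- 1L; nt <- ncol(as.matrix(X1))
    }
    trialspace_dataset(X1, ex, obj[[km$category]],
                       n_electrodes = ne, n_time_samples = nt,
                       exemplar_to_category = obj[[km$exemplar_to_category]])
  } else if (ext == "csv") {
    df <- utils::read.csv(path)
    if (!all(c("exemplar", "category") %in% names(df)))
      stop("csv container missing exemplar/category columns (field: labels)")
    metapath <- paste0(path, ".meta.json")
    X1 <- as.matrix(df[, -(1:2), drop = FALSE])
    dimnames(X1) <- NULL
    if (file.exists(metapath)) {
      meta <- jsonlite::read_json(metapath, simplifyVector = TRUE)
      trialspace_dataset(X1, df$exemplar, df$category,
                         n_electrodes = meta$n_electrodes,
                         n_time_samples = meta$n_time_samples,
                         sampling_rate_hz = meta$sampling_rate_hz,
                         epoch_start_ms = meta$epoch_start_ms)
    } else {
      trialspace_dataset(X1, df$exemplar, df$category,
                         n_electrodes = 1L, n_time_samples = ncol(X1))
    }
  } else stop("unsupported dataset extension: ", ext)
}

validate_loaded <- function(ds) {
  # re-run constructor checks so corrupted files fail loudly
  trialspace_dataset(ds$X1, ds$exemplar_labels, ds$category_labels,
                     n_electrodes = ds$n_electrodes,
                     n_time_samples = ds$n_time_samples,
                     sampling_rate_hz = ds$sampling_rate_hz,
                     epoch_start_ms = ds$epoch_start_ms)
}
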