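#' Overlapping temporal windows over an epoch
#'
#' Generates the sliding-window schedule used by the temporally resolved
#' analyses: windows of `win_len` samples advancing in steps of `step`
#' samples while they fit in the epoch. With the default 62.5 Hz sampling
#' (16 ms per sample) the default schedule over a 32-sample epoch is nine
#' 6-sample (80 ms) windows advancing by 3 samples (48 ms). Window labels in
#' milliseconds are inclusive first-to-last-sample spans:
#' `[start * period, (start + win_len - 1) * period]`, e.g. samples 9-14 are
#' labelled 144-224 ms.
#'
#' @param n_samples epoch length in samples (default 32).
#' @param win_len window length in samples (default 6).
#' @param step advance in samples (default 3).
#' @param sampling_rate_hz sampling rate, for the ms labels (default 62.5).
#' @return data frame with one row per window: `start`, `stop` (half-open,
#'   0-based sample indices), `start_ms`, `end_ms`.
#' @export
temporal_windows <- function(n_samples = 32, win_len = 6, step = 3,
                             sampling_rate_hz = 62.5) {
  if (step <= 0) stop("step must be positive")
  if (win_len > n_samples) stop("window longer than epoch")
  period <- 1000 / sampling_rate_hz
  starts <- seq.int(0L, n_samples - win_len, by = step)
  data.frame(window = seq_along(starts),
             start = starts, stop = starts + win_len,
             start_ms = starts * period,
             end_ms = (starts + win_len - 1L) * period)
}

# seeds for independent searchlight cells, derived from the master seed and
# kept inside the 32-bit integer range
derive_seed <- function(master, cell) {
  as.integer((as.double(master) * 7919 + cell * 104729) %% .Machine$integer.max)
}

run_cell <- function(ds, sel, level, cfg, seed) {
  cell_cfg <- cfg
  cell_cfg$seed <- seed
  tryCatch(crossvalidate(select_features(ds, sel), level, cell_cfg),
           error = function(e) e)
}

cell_row <- function(result, alpha) {
  if (inherits(result, "error"))
    return(data.frame(accuracy = NA_real_, p = NA_real_, d = NA_real_,
                      error = conditionMessage(result)))
  rep <- classification_report(result, alpha)
  data.frame(accuracy = rep$accuracy, p = rep$p, d = rep$d,
             error = NA_character_)
}

#' Spatially resolved decoding: one classification per electrode
#'
#' Runs a full cross-validated classification on each electrode's complete
#' time course (K = samples-per-epoch features each), producing a rate map
#' of accuracies over electrodes. Each electrode gets an independent fold
#' randomization derived from the master seed. A failing cell (e.g. SVD
#' non-convergence) is recorded as a missing accuracy with its error message,
#' without aborting the map.
#'
#' @param ds a `trialspace_dataset`.
#' @param level `"category"` or `"exemplar"`.
#' @param cfg a [cv_config()]; `cfg$seed` is the master seed.
#' @param alpha significance level for the per-cell binomial report.
#' @return An object of class `rate_map`: data frame `cells` with columns
#'   `electrode`, `accuracy`, `p`, `d`, `error`; plus `threshold` (the
#'   significance threshold in percent) and `mode = "electrode"`.
#' @export
per_electrode <- function(ds, level = c("category", "exemplar"),
                          cfg = cv_config(), alpha = 0.01) {
  stopifnot(inherits(ds, "trialspace_dataset"))
  level <- match.arg(level)
  rows <- lapply(seq_len(ds$n_electrodes), function(e) {
    sel <- feature_selector(e, 0L, ds$n_time_samples)
    res <- run_cell(ds, sel, level, cfg, derive_seed(cfg$seed, e))
    cbind(data.frame(electrode = e), cell_row(res, alpha))
  })
  cells <- do.call(rbind, rows)
  n_classes <- length(unique(if (level == "category") ds$category_labels
                             else ds$exemplar_labels))
  structure(list(cells = cells, mode = "electrode", level = level,
                 threshold = significance_threshold(
                   nrow(ds$X1), cfg$n_folds_outer, 1 / n_classes, alpha)),
            class = "rate_map")
}

#' Temporally resolved decoding with full representational chain per window
#'
#' For each sliding temporal window (all electrodes together), runs the
#' cross-validated classification and the downstream representational
#' analyses: confusion matrix, similarity space, classical MDS embedding,
#' and UPGMA dendrogram.
#'
#' @inheritParams per_electrode
#' @param windows a [temporal_windows()] schedule (default: the standard
#'   6-sample / 3-step schedule for the dataset's epoch length).
#' @return An object of class `window_chain`: `windows` (the schedule with
#'   accuracy/p/d columns appended) and `results`, a list per window with
#'   members `decoding`, `similarity`, `embedding`, `dendrogram` (all `NULL`
#'   with an `error` message if the cell failed).
#' @export
per_window <- function(ds, level = c("category", "exemplar"),
                       cfg = cv_config(), windows = NULL, alpha = 0.01) {
  stopifnot(inherits(ds, "trialspace_dataset"))
  level <- match.arg(level)
  if (is.null(windows))
    windows <- temporal_windows(ds$n_time_samples,
                                sampling_rate_hz = ds$sampling_rate_hz)
  results <- vector("list", nrow(windows))
  stat_rows <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    sel <- feature_selector(seq_len(ds$n_electrodes),
                            windows$start[w], windows$stop[w])
    res <- run_cell(ds, sel, level, cfg, derive_seed(cfg$seed, 1000L + w))
    stat_rows[[w]] <- cell_row(res, alpha)
    if (inherits(res, "error")) {
      results[[w]] <- list(error = conditionMessage(res))
    } else {
      # a window may decode a class to a zero diagonal (no correct trials),
      # which leaves the representational chain undefined for that window;
      # keep the decoding and record the cause
      chain <- tryCatch({
        sim <- confusion_to_distance(res$confusion)
        list(similarity = sim, embedding = classical_mds(sim),
             dendrogram = upgma(sim))
      }, error = function(e) list(error = conditionMessage(e)))
      results[[w]] <- c(list(decoding = res), chain)
    }
  }
  structure(list(windows = cbind(windows, do.call(rbind, stat_rows)),
                 results = results, level = level),
            class = "window_chain")
}

#' Spatiotemporally resolved decoding: electrode x window rate map
#'
#' One cross-validated classification per (electrode, temporal window) cell,
#' each on `win_len` single-electrode samples; the candidate component count
#' is automatically capped at the cell's feature count.
#'
#' @inheritParams per_window
#' @return A `rate_map` whose `cells` data frame has columns `electrode`,
#'   `window`, `start_ms`, `end_ms`, `accuracy`, `p`, `d`, `error`;
#'   `mode = "electrode_window"`.
#' @export
per_electrode_window <- function(ds, level = c("category", "exemplar"),
                                 cfg = cv_config(), windows = NULL,
                                 alpha = 0.01) {
  stopifnot(inherits(ds, "trialspace_dataset"))
  level <- match.arg(level)
  if (is.null(windows))
    windows <- temporal_windows(ds$n_time_samples,
                                sampling_rate_hz = ds$sampling_rate_hz)
  rows <- list()
  for (e in seq_len(ds$n_electrodes)) {
    for (w in seq_len(nrow(windows))) {
      sel <- feature_selector(e, windows$start[w], windows$stop[w])
      res <- run_cell(ds, sel, level, cfg,
                      derive_seed(cfg$seed, e * 10000L + w))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(electrode = e, window = windows$window[w],
                   start_ms = windows$start_ms[w],
                   end_ms = windows$end_ms[w]),
        cell_row(res, alpha))
    }
  }
  cells <- do.call(rbind, rows)
  n_classes <- length(unique(if (level == "category") ds$category_labels
                             else ds$exemplar_labels))
  structure(list(cells = cells, mode = "electrode_window", level = level,
                 threshold = significance_threshold(
                   nrow(ds$X1), cfg$n_folds_outer, 1 / n_classes, alpha)),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  ok <- !is.na(x$cells$accuracy)
  cat(sprintf(paste0(
    "%s-level searchlight rate map (%s): %d cells (%d failed)\n",
    "  accuracy range %.2f%% - %.2f%%; alpha threshold %.2f%%\n"),
    x$level, x$mode, nrow(x$cells), sum(!ok),
    100 * min(x$cells$accuracy[ok]), 100 * max(x$cells$accuracy[ok]),
    x$threshold))
  invisible(x)
}
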