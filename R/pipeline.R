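#' Describe one analysis in a pipeline run
#'
#' The standard recipes are category-level (all 6 categories), exemplar-level
#' (all exemplars), within-category exemplar decoding (exemplars of one
#' category), and between-category decoding (2 categories at the category
#' level).
#'
#' @param name directory-safe analysis name.
#' @param level `"category"` or `"exemplar"`.
#' @param categories optional category subset to restrict trials to.
#' @param searchlight character subset of
#'   `c("electrode", "window", "electrode_window")`; searchlight variants to
#'   run in addition to the full-feature classification.
#' @return list of class `analysis_spec`.
#' @export
analysis_spec <- function(name, level = c("category", "exemplar"),
                          categories = NULL, searchlight = character()) {
  level <- match.arg(level)
  stopifnot(all(searchlight %in% c("electrode", "window", "electrode_window")))
  structure(list(name = name, level = level, categories = categories,
                 searchlight = searchlight), class = "analysis_spec")
}

write_square_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
}

run_one_analysis <- function(ds, spec, cfg, alpha, out_dir) {
  if (!is.null(spec$categories)) ds <- subset_trials(ds, categories = spec$categories)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- crossvalidate(ds, spec$level, cfg)
  report <- classification_report(res, alpha)
  write_square_csv(res$confusion$normalized, file.path(out_dir, "confusion.csv"))
  utils::write.csv(data.frame(fold = seq_along(res$fold_k), k = res$fold_k,
                              correct = res$fold_correct,
                              test_size = res$fold_size),
                   file.path(out_dir, "folds.csv"), row.names = FALSE)
  sim <- tryCatch(confusion_to_distance(res$confusion), error = function(e) NULL)
  if (!is.null(sim)) {
    write_square_csv(sim$S, file.path(out_dir, "similarity.csv"))
    write_square_csv(as.matrix(sim$D), file.path(out_dir, "distance.csv"))
    n_cls <- nrow(sim$S)
    pairs <- which(lower.tri(diag(n_cls)), arr.ind = TRUE)
    utils::write.csv(data.frame(class_a = sim$classes[pairs[, "col"]],
                                class_b = sim$classes[pairs[, "row"]],
                                distance = as.vector(sim$D)),
                     file.path(out_dir, "distance_condensed.csv"),
                     row.names = FALSE)
    emb <- classical_mds(sim)
    if (ncol(emb$coordinates) > 0L) {
      coords <- as.data.frame(emb$coordinates)
      names(coords) <- paste0("dim", seq_len(ncol(coords)))
      utils::write.csv(cbind(class = emb$classes, coords),
                       file.path(out_dir, "mds.csv"), row.names = FALSE)
      utils::write.csv(data.frame(dimension = seq_along(emb$eigenvalues),
                                  eigenvalue = emb$eigenvalues),
                       file.path(out_dir, "mds_eigenvalues.csv"),
                       row.names = FALSE)
    }
    dend <- upgma(sim)
    dendrogram_newick(dend, file.path(out_dir, "dendrogram.newick"))
    utils::write.csv(data.frame(merge_a = dend$merge[, 1L],
                                merge_b = dend$merge[, 2L],
                                height = dend$height),
                     file.path(out_dir, "merges.csv"), row.names = FALSE)
    reord <- reorder_confusion(res$confusion, dend)
    write_square_csv(reord$normalized,
                     file.path(out_dir, "confusion_reordered.csv"))
  }
  jsonlite::write_json(report, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  for (mode in spec$searchlight) {
    map <- switch(mode,
      electrode = per_electrode(ds, spec$level, cfg, alpha),
      window = per_window(ds, spec$level, cfg, alpha = alpha),
      electrode_window = per_electrode_window(ds, spec$level, cfg,
                                              alpha = alpha))
    tab <- if (mode == "window") map$windows else map$cells
    utils::write.csv(tab, file.path(out_dir, paste0("ratemap_", mode, ".csv")),
                     row.names = FALSE)
  }
  report
}

#' Run the full decoding and RSA pipeline over participants
#'
#' Processes each participant's dataset independently: for every analysis in
#' `analyses`, runs the cross-validated classification, derives the
#' representational similarity space, MDS embedding and UPGMA dendrogram,
#' optionally the searchlight maps, and writes all outputs under
#' `out_dir/<participant>/<analysis>/`. A cross-participant summary mirrors
#' the usual report table: mean accuracy, exact binomial p and effect size
#' computed from the floored mean per-fold correct count, and the unbiased
#' sample standard deviation across participants. A failing analysis for one
#' participant is recorded and excluded from that analysis's summary with an
#' explicit participant count.
#'
#' @param participants a named list; each element is either a
#'   `trialspace_dataset`, a dataset path for [load_dataset()], or a
#'   [generator_config()] to simulate from.
#' @param analyses list of [analysis_spec()]s.
#' @param cfg a [cv_config()]; each participant/analysis gets an independent
#'   fold randomization derived from `cfg$seed`.
#' @param alpha significance level (default 0.01).
#' @param out_dir output directory; created if needed.
#' @return invisibly, a list with `summary` (data frame) and `reports`
#'   (nested per participant/analysis). Writes `summary.csv` and
#'   `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(participants, analyses, cfg = cv_config(),
                         alpha = 0.01, out_dir = "eegrsa_results") {
  if (is.null(names(participants)))
    names(participants) <- sprintf("participant%02d", seq_along(participants))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- list()
  manifest <- list(master_seed = cfg$seed, alpha = alpha, runs = list())
  for (pi in seq_along(participants)) {
    pname <- names(participants)[pi]
    p <- participants[[pi]]
    ds <- if (inherits(p, "trialspace_dataset")) p
          else if (inherits(p, "generator_config")) simulate_dataset(p)
          else load_dataset(p)
    for (ai in seq_along(analyses)) {
      spec <- analyses[[ai]]
      run_cfg <- cfg
      run_cfg$seed <- derive_seed(cfg$seed, pi * 100L + ai)
      odir <- file.path(out_dir, pname, spec$name)
      rep <- tryCatch(run_one_analysis(ds, spec, run_cfg, alpha, odir),
                      error = function(e) list(error = conditionMessage(e)))
      reports[[pname]][[spec$name]] <- rep
      manifest$runs[[length(manifest$runs) + 1L]] <- list(
        participant = pname, analysis = spec$name, seed = run_cfg$seed,
        failed = !is.null(rep$error),
        fold_k = rep$fold_k, fold_correct = rep$fold_correct)
    }
  }
  summary <- do.call(rbind, lapply(analyses, function(spec) {
    reps <- lapply(reports, `[[`, spec$name)
    ok <- vapply(reps, function(r) is.null(r$error), logical(1L))
    reps <- reps[ok]
    if (length(reps) == 0L)
      return(data.frame(analysis = spec$name, n_participants = 0L,
                        mean_accuracy = NA_real_, p = NA_real_, d = NA_real_,
                        s = NA_real_, threshold = NA_real_))
    accs <- vapply(reps, `[[`, numeric(1L), "accuracy")
    # group-level inference from the floored mean per-fold correct count
    c_fold <- floor(mean(vapply(reps, `[[`, numeric(1L), "c_fold")))
    n_fold <- reps[[1L]]$n_fold
    chance <- reps[[1L]]$chance
    p <- stats::pbinom(c_fold - 1, n_fold, chance, lower.tail = FALSE)
    d <- (c_fold - n_fold * chance) / sqrt(n_fold * chance * (1 - chance))
    data.frame(analysis = spec$name, n_participants = length(reps),
               mean_accuracy = mean(accs), p = p, d = d,
               s = if (length(accs) >= 2L) sample_std(accs) else NA_real_,
               threshold = reps[[1L]]$threshold_at_alpha)
  }))
  utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(summary = summary, reports = reports))
}
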