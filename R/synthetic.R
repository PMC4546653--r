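#' Configuration for the synthetic trial-space generator
#'
#' Describes a simulated visual-object EEG experiment: a set of image
#' exemplars organized into categories and superordinates, each level
#' contributing a spatiotemporal signal template, plus per-trial noise. The
#' defaults mirror a dense-array recording of 72 object photographs (6
#' categories x 12 exemplars, 72 trials each) epoched to 32 samples at
#' 62.5 Hz over 124 electrodes, with the category hierarchy
#' Animate = \{Human Body, Human Face, Animal Body, Animal Face\} and
#' Inanimate = \{Fruit Vegetable, Inanimate Object\}.
#'
#' The variance components set the expected squared amplitude of the
#' superordinate-, category- and exemplar-level templates (in squared voltage
#' units, matching `var_noise`), so category separability is controlled
#' directly: e.g. `var_category` large relative to `var_noise` yields highly
#' decodable categories.
#'
#' @param n_electrodes,n_time_samples epoch geometry (defaults 124 x 32).
#' @param sampling_rate_hz sampling rate (default 62.5).
#' @param n_categories,n_exemplars_per_category,n_trials_per_exemplar design
#'   counts (defaults 6, 12, 72).
#' @param hierarchy integer vector of length `n_categories` assigning each
#'   category to a superordinate. Default: categories 1-4 to superordinate 1
#'   (animate), the rest to superordinate 2 (inanimate).
#' @param var_superordinate,var_category,var_exemplar,var_noise nonnegative
#'   variance components; signal defaults 0, noise 1.
#' @param signal_electrodes optional electrode subset carrying signal
#'   (templates are zero elsewhere).
#' @param signal_window optional length-2 half-open 0-based sample window
#'   `c(start, stop)` carrying signal.
#' @param temporal_smoothness moving-average length (in samples) applied to
#'   template time courses; 1 = white. Default 4 (a 64 ms smoothing window at
#'   62.5 Hz, the scale of a transient evoked component).
#' @param noise_model `"iid"` (default) or `"ar1"` for temporally and
#'   spatially correlated noise.
#' @param noise_ar,noise_spatial AR(1) coefficient in time and neighbour
#'   correlation across the electrode index, used when `noise_model = "ar1"`.
#' @param seed RNG seed for reproducible template and trial draws.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_electrodes = 124, n_time_samples = 32,
                             sampling_rate_hz = 62.5,
                             n_categories = 6, n_exemplars_per_category = 12,
                             n_trials_per_exemplar = 72,
                             hierarchy = NULL,
                             var_superordinate = 0, var_category = 0,
                             var_exemplar = 0, var_noise = 1,
                             signal_electrodes = NULL, signal_window = NULL,
                             temporal_smoothness = 4,
                             noise_model = c("iid", "ar1"),
                             noise_ar = 0.5, noise_spatial = 0.5,
                             seed = 1L) {
  counts <- c(n_electrodes, n_time_samples, n_categories,
              n_exemplars_per_category, n_trials_per_exemplar)
  if (any(counts < 1)) stop("invalid config: all counts must be >= 1")
  vars <- c(var_superordinate, var_category, var_exemplar, var_noise)
  if (any(vars < 0)) stop("invalid config: variances must be >= 0")
  if (is.null(hierarchy)) {
    hierarchy <- ifelse(seq_len(n_categories) <= ceiling(2 * n_categories / 3), 1L, 2L)
    if (n_categories == 1L) hierarchy <- 1L
  }
  if (length(hierarchy) != n_categories)
    stop("invalid config: hierarchy must assign every category a superordinate")
  if (!is.null(signal_window)) {
    signal_window <- as.integer(signal_window)
    if (length(signal_window) != 2L || signal_window[1L] < 0L ||
        signal_window[2L] > n_time_samples || signal_window[2L] <= signal_window[1L])
      stop("invalid config: signal_window must be a half-open window within the epoch")
  }
  if (!is.null(signal_electrodes)) {
    signal_electrodes <- as.integer(signal_electrodes)
    if (any(signal_electrodes < 1L) || any(signal_electrodes > n_electrodes))
      stop("invalid config: signal_electrodes out of bounds")
  }
  if (temporal_smoothness < 1) stop("invalid config: temporal_smoothness must be >= 1")
  structure(list(
    n_electrodes = as.integer(n_electrodes),
    n_time_samples = as.integer(n_time_samples),
    sampling_rate_hz = sampling_rate_hz,
    n_categories = as.integer(n_categories),
    n_exemplars_per_category = as.integer(n_exemplars_per_category),
    n_trials_per_exemplar = as.integer(n_trials_per_exemplar),
    hierarchy = as.integer(hierarchy),
    var_superordinate = var_superordinate, var_category = var_category,
    var_exemplar = var_exemplar, var_noise = var_noise,
    signal_electrodes = signal_electrodes, signal_window = signal_window,
    temporal_smoothness = as.integer(temporal_smoothness),
    noise_model = match.arg(noise_model),
    noise_ar = noise_ar, noise_spatial = noise_spatial,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Design dimensions implied by a generator configuration
#'
#' @param config a [generator_config()].
#' @return list with `n_trials` (categories x exemplars per category x trials
#'   per exemplar) and `n_features` (electrodes x samples).
#' @export
generator_dimensions <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  list(
    n_trials = config$n_categories * config$n_exemplars_per_category *
      config$n_trials_per_exemplar,
    n_features = config$n_electrodes * config$n_time_samples
  )
}

# temporally smoothed zero-mean template with per-entry variance `v`,
# masked outside the configured signal electrodes/window
draw_template <- function(config, v) {
  ne <- config$n_electrodes; nt <- config$n_time_samples
  if (v == 0) return(matrix(0, ne, nt))
  m <- matrix(stats::rnorm(ne * nt), ne, nt)
  L <- config$temporal_smoothness
  if (L > 1L) {
    # circular moving average preserves stationarity; rescale to unit variance
    m <- t(apply(m, 1L, function(x)
      stats::filter(x, rep(1 / L, L), method = "convolution",
                    sides = 2L, circular = TRUE))) * sqrt(L)
  }
  m <- m * sqrt(v)
  if (!is.null(config$signal_electrodes)) {
    mask <- rep(TRUE, ne); mask[config$signal_electrodes] <- FALSE
    m[mask, ] <- 0
  }
  if (!is.null(config$signal_window)) {
    keep <- seq.int(config$signal_window[1L] + 1L, config$signal_window[2L])
    m[, -keep] <- 0
  }
  m
}

#' Draw the planted hierarchy of signal templates
#'
#' Generates one spatiotemporal template (electrodes x samples) per
#' superordinate, per category, and per exemplar, with variances as
#' configured. An exemplar's expected evoked pattern is the sum of its
#' superordinate, category and exemplar templates, so trial data carry a
#' three-level similarity structure that downstream clustering should
#' recover.
#'
#' @param config a [generator_config()].
#' @return An object of class `template_set`: lists `superordinate`,
#'   `category`, `exemplar` of template matrices, plus the exemplar/category/
#'   superordinate assignment vectors.
#' @export
make_templates <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_ex <- config$n_categories * config$n_exemplars_per_category
  exemplar_category <- rep(seq_len(config$n_categories),
                           each = config$n_exemplars_per_category)
  withr_seed(config$seed, {
    supers <- lapply(seq_len(max(config$hierarchy)), function(i)
      draw_template(config, config$var_superordinate))
    cats <- lapply(seq_len(config$n_categories), function(i)
      draw_template(config, config$var_category))
    exs <- lapply(seq_len(n_ex), function(i)
      draw_template(config, config$var_exemplar))
    structure(list(superordinate = supers, category = cats, exemplar = exs,
                   exemplar_category = exemplar_category,
                   category_superordinate = config$hierarchy),
              class = "template_set")
  })
}

#' Expected evoked pattern of one exemplar
#'
#' @param templates a [make_templates()] result.
#' @param exemplar exemplar index.
#' @return electrodes x samples matrix: superordinate + category + exemplar
#'   template sum.
#' @export
exemplar_pattern <- function(templates, exemplar) {
  stopifnot(inherits(templates, "template_set"))
  cat <- templates$exemplar_category[exemplar]
  sup <- templates$category_superordinate[cat]
  templates$superordinate[[sup]] + templates$category[[cat]] +
    templates$exemplar[[exemplar]]
}

#' Simulate a trial-space dataset with planted category structure
#'
#' Draws the template hierarchy from `config`, then generates
#' `n_trials_per_exemplar` noisy trials per exemplar: each trial is the
#' exemplar's expected pattern plus zero-mean noise of variance `var_noise`
#' (i.i.d. by default; optionally AR(1) in time with spatially correlated
#' electrodes), reshaped to a trial-space feature row in electrode-major
#' order. One call generates one "participant"; generate multiple
#' participants by varying `seed`.
#'
#' @param config a [generator_config()].
#' @param max_elements guard against accidentally huge simulations: error if
#'   the trial matrix would exceed this many entries (default 2^28, i.e. 2 GiB
#'   of doubles).
#' @return A [trialspace_dataset()] with balanced exemplar and category
#'   labels.
#' @export
simulate_dataset <- function(config, max_elements = 2^28) {
  stopifnot(inherits(config, "generator_config"))
  dims <- generator_dimensions(config)
  if (as.double(dims$n_trials) * dims$n_features > max_elements)
    stop(sprintf("requested dataset of %d x %d entries exceeds max_elements = %g",
                 dims$n_trials, dims$n_features, max_elements))
  templates <- make_templates(config)
  n_ex <- config$n_categories * config$n_exemplars_per_category
  ntr <- config$n_trials_per_exemplar
  ne <- config$n_electrodes; nt <- config$n_time_samples
  exemplar_labels <- rep(seq_len(n_ex), each = ntr)
  category_labels <- templates$exemplar_category[exemplar_labels]
  X1 <- matrix(0, dims$n_trials, dims$n_features)
  withr_seed(config$seed + 1L, {
    for (ex in seq_len(n_ex)) {
      pattern <- as.vector(t(exemplar_pattern(templates, ex)))  # electrode-major
      rows <- ((ex - 1L) * ntr + 1L):(ex * ntr)
      noise <- draw_noise(config, ntr)
      X1[rows, ] <- matrix(pattern, ntr, dims$n_features, byrow = TRUE) + noise
    }
  })
  trialspace_dataset(X1, exemplar_labels, category_labels,
                     n_electrodes = ne, n_time_samples = nt,
                     sampling_rate_hz = config$sampling_rate_hz)
}

# n trials of noise, each a flattened electrode-major epoch
draw_noise <- function(config, n) {
  ne <- config$n_electrodes; nt <- config$n_time_samples
  K <- ne * nt
  if (config$var_noise == 0) return(matrix(0, n, K))
  sd0 <- sqrt(config$var_noise)
  if (config$noise_model == "iid")
    return(matrix(stats::rnorm(n * K, sd = sd0), n, K))
  # AR(1) along time within each electrode, then mixing across neighbouring
  # electrodes; both stages are variance-preserving
  phi <- config$noise_ar; rho <- config$noise_spatial
  out <- matrix(0, n, K)
  for (t in seq_len(n)) {
    m <- matrix(stats::rnorm(ne * nt), ne, nt)
    if (phi != 0) {
      for (j in 2:nt) m[, j] <- phi * m[, j - 1L] + sqrt(1 - phi^2) * m[, j]
    }
    if (rho != 0 && ne > 1L) {
      sm <- m
      for (e in seq_len(ne)) {
        nb <- intersect(c(e - 1L, e + 1L), seq_len(ne))
        sm[e, ] <- sqrt(1 - rho^2) * m[e, ] +
          rho * colMeans(m[nb, , drop = FALSE])
      }
      m <- sm
    }
    out[t, ] <- as.vector(t(m)) * sd0
  }
  out
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
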