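---
title: "Decoding and representational similarity analysis with eegrsa: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding and representational similarity analysis with eegrsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegrsa)
```

This vignette documents the statistical machinery of `eegrsa`, the
conventions it commits to where the underlying methods leave choices open,
and what its synthetic-data tests do and do not establish about real EEG.

## The data model

An analysis starts from a trial-space matrix `X1` with one row per
experimental trial. Each row is the electrode-major concatenation of that
trial's epoch: electrode `e`'s full time course occupies contiguous columns
`(e-1)*nTimeSamples + 1 : e*nTimeSamples`. The canonical geometry is a
dense-array visual-object experiment — 124 retained electrodes, 32 samples
per epoch at 62.5 Hz (496 ms of post-stimulus response, 16 ms per sample),
giving feature vectors of length 3,968; 72 image exemplars in six categories
(Human Body, Human Face, Animal Body, Animal Face, Fruit/Vegetable,
Inanimate Object), 72 trials per exemplar, 5,184 trials per participant —
but every function takes the geometry from the dataset object, so any
electrode/sample/class layout works.

Electrode-major ordering (rather than sample-major) is a contract, not a
convenience: searchlight feature subsetting (`select_features()`) and the
inverse reshape both depend on it, and the tests pin it with brute-force
column-index enumeration.

Sample windows are half-open, 0-based internally. Reported window labels in
milliseconds are inclusive first-to-last-sample spans: a 6-sample window
starting at sample 9 is labelled 144–224 ms at 62.5 Hz. This reconciles
"80 ms long" with 6 samples: the span from the first to the last included
sample is 5 × 16 = 80 ms.

## The decoder

Classification is one-against-all LDA in principal-component space:

1. `svd_rotate()` computes the thin SVD `X1 = UΣVᵀ` and rotates trials to
   component scores `X1 V = UΣ`. Components are ordered by descending
   singular value; each basis column's sign is fixed so that its
   largest-magnitude entry is positive, making downstream results
   deterministic.
2. For each class `c`, `lda_fit()` fits the two-class Fisher discriminant of
   `c` against the pooled remainder: `w_c = S_w^{-1}(μ_c − μ_rest)` with
   `S_w` the pooled within-group covariance, bias at the midpoint of the
   group means. `lda_predict()` assigns the argmax of the per-class scores;
   exact ties go to the lowest class index.
3. `crossvalidate()` runs ten-fold outer cross-validation. Fold assignment
   is a plain random permutation split into blocks of `floor(n/10)` trials,
   remainders assigned to the first `n mod 10` folds (so 5,184 trials give
   four folds of 519 and six of 518). Within each outer fold, a nested
   ten-fold inner cross-validation on the training partitions alone selects
   the number of components `k` from a candidate grid in
   `[3, min(200, K)]`; ties go to the smallest `k`. Every trial is tested
   exactly once and predictions aggregate into one confusion matrix.

Two conventions deserve emphasis:

* **The SVD is computed once on the full matrix before partitioning.** This
  reproduces the established analysis convention and is much cheaper, but it
  shares unsupervised structure between training and test folds.
  `cv_config(fold_safe_svd = TRUE)` recomputes the SVD per outer training
  fold for users who prefer strict fold hygiene. The default is the
  reproduction-faithful variant.
* **The component grid is a declared default, not an inference.** For short
  feature vectors (`K ≤ 32`) the grid is every integer in `[3, min(200,K)]`;
  otherwise a 24-point log-spaced grid. An explicit `k_grid` overrides both;
  exhaustive search is available at its computational price. Candidates
  exceeding the available rank are truncated with a warning.

Degenerate inputs fail loudly: non-finite data, a singular pooled covariance
(the error suggests the `shrinkage` ridge), classes with fewer than two
training trials, unbalanced designs (overridable with
`allow_unbalanced = TRUE`; accuracy-as-mean-diagonal and chance = 1/N both
assume balance).

## From confusions to distances

The confusion matrix is normalized row-stochastically (`counts / row sum`),
so entry `(i, j)` estimates `P(predicted j | actual i)` and the diagonal
carries per-class discriminability — information that pairwise-correlation
RDMs (diagonal identically 1) and pairwise-classifier RDMs (diagonal
undefined) do not have. The similarity chain is:

* `self_normalize()`: `CM′_ij = CM_ij / CM_ii`, giving unit self-similarity.
  A zero diagonal (a class never correctly predicted) leaves the chain
  undefined; the error names the offending class so the caller can merge or
  drop it. In the searchlight per-window chain this is caught per window and
  recorded rather than aborting the schedule.
* `symmetrize_similarity()`: the **elementwise** geometric mean
  `S_ij = √(CM′_ij · CM′_ji)`. The elementwise reading (not a matrix-product
  root) is the standard confusion-symmetrization and the only one that
  preserves the unit diagonal.
* `to_distance()`: `D = ℒ(1 − S)`, the condensed lower-triangle vector in
  the `stats::dist` ordering used by every downstream consumer. When an
  off-diagonal confusion exceeds its row diagonal, `S_ij > 1` and the raw
  distance is negative; such distances are clipped to 0 and the result is
  flagged (`clipped = TRUE`), since MDS and UPGMA require nonnegative
  dissimilarities. Clipping is rare in practice — it requires a class to be
  confused with another more often than it is correctly classified.

## Embedding and clustering

`classical_mds()` implements Torgerson scaling: double-center the squared
distances, `B = −½ J D² J`, eigendecompose, keep eigenvalues above a
relative tolerance of `1e-10`, and scale eigenvectors by the square roots of
the eigenvalues. Dimensions are ordered by descending eigenvalue; each
dimension's sign is fixed so its largest-magnitude coordinate is positive.
Non-Euclidean distance sets simply lose their negative directions (the count
is reported as `n_negative`); an all-zero distance set yields a 0-dimensional
embedding rather than an error. `stats::cmdscale` is used as an independent
cross-check in the tests, never as the implementation, because the package
pins truncation and sign conventions that `cmdscale` leaves open.

`upgma()` is group-average agglomeration: merge the pair of clusters with
the smallest mean inter-member distance, at a height equal to that mean
(the full linkage distance, not a half-height — the dominant
scientific-computing convention; cophenetic-based tests are covariant in
this choice). Ties break toward the lexicographically smallest pair of
lowest original leaf indices, making trees deterministic; with all-equal
distances the first merge is always leaves (1, 2). Heights are
nondecreasing and cophenetic distances ultrametric; both properties, and
agreement with a brute-force O(N³) oracle and with
`hclust(method = "average")`, are asserted in the tests. Dendrograms export
to Newick via `ape` and drive `reorder_confusion()`, which permutes a
confusion matrix into leaf order to expose block structure.

## Inference

Significance of an accuracy is computed under the null that each test
classification is an independent Bernoulli trial at chance `1/nClasses`,
parameterized per fold: `nFold = floor(nTrials/10)` attempts and
`cFold = floor(totalCorrect/10)` successes, with exact upper-tail
probability `P(X ≥ cFold)` and effect size `d = (cFold − nFold·chance)/σ`.
Flooring both parameters is deliberate and matches the reporting convention
the package reproduces.

`significance_threshold()` returns `100·k*/nFold` where `k*` is the exact
binomial upper quantile (smallest `k` with CDF ≥ 1 − α). This single rule
reproduces the three canonical α = 0.01 thresholds — 20.66% (six-class,
fold 518, chance 1/6), 16.28% (twelve-class, fold 86, chance 1/12), 58.72%
(two-class, fold 172, chance 1/2) — which the alternative rule "smallest
`k` with `P(X ≥ k) < α`" does not. One boundary subtlety follows from the
quantile rule: the threshold count itself can have an exceedance
probability marginally above α (e.g. `P(X ≥ 107) = 0.0101` at fold 518,
chance 1/6); counts *above* the threshold are always significant. The
package treats the quantile rule as the contract.

Searchlight maps deliberately apply **no multiple-comparison correction**,
matching the reporting convention of per-cell rate maps; the per-cell
binomial reports carry everything needed to apply one.

Category separability along MDS dimensions uses two-tailed Wilcoxon
rank-sum tests (`stats::wilcox.test`), exact when both groups have ≤ 12
members and tie-free data — the canonical group size is 12 exemplars per
category — and the tie-corrected normal approximation otherwise.
Cross-participant dispersion is the unbiased (n − 1) sample standard
deviation.

## The synthetic generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, not EEG biophysics. A three-level hierarchy of signal templates —
one per superordinate, category, and exemplar, each an electrodes × samples
matrix — is drawn as temporally smoothed Gaussian noise (circular moving
average of length `temporal_smoothness`, default 4 samples ≈ 64 ms,
variance-preserving, mimicking the band-limited character of evoked
components). An exemplar's expected pattern is the sum of its three
templates, with variances `var_superordinate`, `var_category`,
`var_exemplar` setting expected squared amplitudes in the same units as
`var_noise`. Trials are pattern + noise; noise is i.i.d. Gaussian by
default — the simplest testable model — with an optional AR(1)-in-time,
spatially correlated mode for searchlight realism. `signal_electrodes` and
`signal_window` zero the templates outside a known region, giving
searchlight tests a planted ground truth. The default design counts mirror
the canonical experiment (6 × 12 × 72 over 124 × 32); one call generates
one participant, multiple participants come from varying `seed`.

What the generator does **not** emulate: volume-conducted spatial
correlation of real scalp fields (except crudely in the AR(1) mode),
per-exemplar low-level image-feature confounds, trial-order and session
effects, artifacts. Passing tests therefore demonstrate that the pipeline
recovers structure *that is present in the planted form*, not that real EEG
contains such structure.

## Problem sizes and calibration behavior of the tests

The test suite runs on deliberately small instances (typically 4–8
electrodes, 8–32 samples, 120–720 trials, compact component grids) chosen
to exercise every code path in seconds while keeping the statistical
properties interpretable:

* **Null calibration** is checked on 6-class, 240-trial zero-signal
  datasets: over 50 seeded runs, ≥ 95% of total-correct counts must fall in
  the central 99% band of Binomial(240, 1/6). At much smaller sizes (120
  trials) cross-validated counts are visibly overdispersed relative to the
  binomial reference — fold-wise training sets overlap, so per-trial
  predictions are not independent — and coverage drops to ~90%. This is a
  property of cross-validation itself, not a defect; the binomial null is
  the declared reporting convention, and at realistic trial counts the
  approximation is comfortable.
* **Planted-structure recovery** is checked in two regimes. With
  `var_category ≫ var_noise`, six-class accuracy exceeds 90% at every seed
  tried. Superordinate recovery (the UPGMA top cut equals the planted
  animate/inanimate-style split) is checked in a superordinate-dominant,
  moderate-accuracy regime (~80–94%): near-ceiling classifiers produce too
  few confusions to estimate the off-diagonal RDM mass reliably, so the two
  properties are strongest in different corners of the SNR space. This is
  worth remembering when interpreting real high-accuracy decodings: the
  representational structure is estimated from errors.
* **Searchlight localization** plants signal at two known electrodes in the
  canonical fourth window (144–224 ms); the grid argmax lands in the
  planted block at every seed tried.

## Known limitations

* The whole-matrix SVD default (above) is faithful to the reproduced
  convention but optimistic; use `fold_safe_svd = TRUE` for strict claims.
* Confusion-derived RDMs need nonzero diagonals; very poor classes must be
  merged or dropped.
* Dataset import reads the package's own RDS/CSV containers and plain
  RDS-serialized list containers with a configurable key map; HDF5/MAT
  containers from other toolboxes must be converted externally (any route
  that produces a trials × features matrix plus label vectors suffices).
* Scalp-topography rendering is out of scope; searchlight output is tabular
  (long-format rate maps with per-cell inference).
* Reported group-level `d` aggregates the floored per-fold correct counts
  across participants; alternative aggregation orders (per-participant `d`
  averaged) give slightly different values and are not reported.
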