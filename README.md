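# eegrsa

Single-trial EEG decoding and Representational Similarity Analysis (RSA)
in R, for researchers who want to recover the representational structure of
visual object categories from scalp-recorded evoked responses.

## What it does

Given a **trial-space matrix** `X1` (rows = single trials, columns = the
electrode-major concatenation of each epoch's per-electrode time courses —
e.g. 124 electrodes × 32 samples at 62.5 Hz = 3,968 features), labelled by
image exemplar and category, the package:

1. **Decodes** the labels with one-against-all Linear Discriminant Analysis
   after a principal-component rotation (`X1 = UΣVᵀ`, classify in `UΣ`),
   with ten-fold cross-validation and a nested ten-fold inner loop that
   selects the number of components `k ∈ [3, min(200, K)]`. The result is a
   row-stochastic confusion matrix `CM` (rows = actual, columns = predicted;
   accuracy = mean diagonal).
2. **Builds an RDM from the multi-class confusion matrix** — the package's
   core method. Unlike pairwise-correlation (diagonal ≡ 1) or
   pairwise-classifier (diagonal undefined) RDMs, a multi-class confusion
   matrix carries per-class self-similarity on its diagonal. The chain is

   &nbsp;&nbsp;`CM′ᵢⱼ = CMᵢⱼ / CMᵢᵢ` (unit self-similarity) →
   `Sᵢⱼ = √(CM′ᵢⱼ · CM′ⱼᵢ)` (geometric-mean symmetrization) →
   `D = ℒ(1 − S)` (condensed distance vector).
3. **Explores the representational space** with classical (Torgerson) MDS
   (dimensions ordered by descending eigenvalue) and UPGMA hierarchical
   clustering (dendrograms, Newick export, dendrogram-reordered confusion
   matrices).
4. **Runs searchlight variants**: per-electrode, per temporal window
   (default 6-sample/80 ms windows advancing by 3 samples/48 ms), and
   per electrode × window, each cell a full cross-validated classification.
5. **Quantifies significance** with exact binomial inference on the floored
   per-fold correct count: p-values, effect sizes
   `d = (C_obs − C₀)/σ`, significance thresholds (e.g. 20.66% for six-class
   decoding of 5,184 trials at α = 0.01), cross-participant sample SD, and
   Wilcoxon rank-sum separability of categories along MDS dimensions.

A synthetic-data generator (`generator_config()` / `simulate_dataset()`)
plants a superordinate → category → exemplar hierarchy of smooth
spatiotemporal templates in noisy multi-electrode epochs, so the entire
pipeline is testable end-to-end without access to recorded EEG.

## Worked example

Simulate one "participant" whose categories 1–4 share an animate-like
superordinate template and categories 5–6 an inanimate-like one, decode the
six categories, and recover the planted hierarchy:

```r
library(eegrsa)
cfg <- generator_config(n_electrodes = 8, n_time_samples = 16,
                        n_exemplars_per_category = 2,
                        n_trials_per_exemplar = 60,
                        var_superordinate = 4, var_category = 1,
                        var_noise = 18, seed = 62)
ds  <- simulate_dataset(cfg)
res <- crossvalidate(ds, "category", cv_config(seed = 62, k_grid = c(3, 8, 16)))
res
#> category-level decoding: 6 classes, 720 trials, 10-fold CV
#>   accuracy 90.56% (chance 16.67%); components per fold: 16 16 16 16 16 16 16 16 16 16

binomial_pvalue(sum(res$fold_correct), nrow(ds$X1), 10, 1/6)
#> Accuracy 90.56% (chance 16.67%); per-fold 65/72 correct
#>   exact binomial p = 1.11e-42, effect size d = 16.76

significance_threshold(nrow(ds$X1), 10, 1/6, 0.01)
#> [1] 27.78

dend <- upgma(confusion_to_distance(res$confusion))
cat(dendrogram_newick(dend))
#> (((1:0.461,3:0.461):0.028,(2:0.471,4:0.471):0.019):0.010,(5:0.475,6:0.475):0.024);
top_cut(dend)
#> 1 2 3 4 5 6
#> 1 1 1 1 2 2
```

The decoder recovers the categories far above the 27.78% significance
threshold, and the top cut of the UPGMA dendrogram built from the
confusion-derived RDM separates the planted superordinates exactly.
`classical_mds()` embeds the same distances in coordinates;
`per_electrode()`, `per_window()` and `per_electrode_window()` produce
searchlight rate maps; `run_pipeline()` executes a list of analyses over
multiple participants and writes a results bundle (confusion/similarity/
distance CSVs, MDS coordinates, Newick dendrograms, JSON stats, summary
table, manifest).

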