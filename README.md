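# eegencode

Time-resolved linearized encoding of visual features in epoched EEG, with a
fully synthetic, ground-truth-planted experiment generator so that every stage
of the analysis is testable at desk scale.

## The problem

When the brain processes a natural scene, low-level features (edges), 
mid-level features (surface reflectance, lighting, world normals, scene
depth, body skeletons) and high-level features (action identity) are
extracted at different times — and deep vision networks extract analogous
features at different layers. A standard way to chart this is the
*linearized encoding model*: for each candidate feature, a ridge regression
predicts the measured response (an EEG channel at a timepoint, or a network
component at a layer) from that feature's ground-truth annotation, and the
Pearson correlation between predicted and observed held-out responses traces
out when (or where) the feature is represented. The per-feature peak
latencies and peak layers then give two orderings of the same feature set,
and their Spearman correlation — with an exact 5040-permutation test for 7
features — measures how aligned the temporal hierarchy in the brain is with
the depth hierarchy in the network.

`eegencode` implements the full pipeline for anyone working with epoched,
trial-based electrophysiology and per-stimulus feature annotations:

- **Synthetic experiment generator** — factorial stimulus designs with
  room/viewpoint generalization splits (default 1440 scenes, 1080/180/180),
  seven annotation types in rendering-engine shape classes, forward-model
  EEG (19 channels, −400..980 ms at 50 Hz, 5400/5400/900 trials) with
  feature-specific Gaussian response kernels and spatially correlated noise,
  and eight-layer network-style activations with planted feature-peak layers.
- **Annotation preparation** — row-major flattening, video frame averaging,
  train-fitted PCA (100 components for high-dimensional features; skeleton
  and action keep native dimensions), and a Canny edge detector.
- **Multivariate noise normalization** — Ledoit–Wolf shrinkage estimation of
  the trial-to-trial channel noise covariance from repeated stimuli and
  whitening by its symmetric inverse square root.
- **Pairwise decoding** — linear SVM over pseudotrials (random bins of 5 of
  30 repetitions) with stratified sixfold cross-validation, averaged over all
  scene pairs per timepoint.
- **Ridge encoding** — 30-value log-spaced penalty grid (1e-5..1e15) selected
  on a validation split, per-(channel, timepoint) test correlations,
  variance-weighted layer summaries, and split-half noise ceilings.
- **Resampling inference** — sign-permutation and condition-swap tests,
  Benjamini–Hochberg FDR, bootstrap CIs for means, peak latencies and peak
  differences, and the exact-permutation hierarchy correlation.

Results are tibbles throughout, with `tidy()`, `glance()` and `autoplot()`
methods; raw epochs live in a light `eeg_epochs` container.

## Worked example

A complete single-subject analysis at the default study scale (about a
minute on one core):

```r
library(eegencode)

design      <- make_design(seed = 1)                      # 1440 scenes
annotations <- simulate_annotations(design, seed = 2)     # 7 feature sets
epochs      <- simulate_eeg(design, annotations, seed = 3)
table(epochs$trial_table$split)
#> train       test validation 
#>  5400       5400        900 

white <- mvnn(baseline_correct(epochs))   # Ledoit-Wolf whitening
dm    <- prepare_design_matrices(annotations, design)     # PCA-100 predictors
enc   <- encode_eeg(dm, white)
glance(enc)
#> # A tibble: 7 × 4
#>   feature       peak_ms peak_r  lambda
#>   <chr>           <dbl>  <dbl>   <dbl>
#> 1 action            420  0.886 4.18e13
#> 2 edges              80  0.823 7.88e 1
#> 3 lighting          160  0.667 2.21e 5
#> 4 reflectance       120  0.737 3.86e 2
#> 5 scene_depth       220  0.669 7.88e 1
#> 6 skeleton          260  0.859 1.61e 1
#> 7 world_normals     180  0.643 7.88e 1
```

Every feature's encoding time course peaks at (or within one 20 ms sample of)
its planted latency — edges first at 80 ms, action identity last at 420 ms —
with accuracies of 0.64–0.89 against an upper noise ceiling near 0.9. The
same features encoded into the simulated network activations peak at their
planted layers, and the two orderings agree perfectly:

```r
acts <- simulate_layer_activations(design, annotations, seed = 6)
le   <- encode_layers(dm, prepare_layer_activations(acts, design))
glance(le)[, c("feature", "peak_layer")]   # edges -> "1.0", ..., action -> "4.1"

hier <- hierarchy_correlation(glance(enc)$peak_ms, glance(le)$peak_index)
tidy(hier)
#> # A tibble: 1 × 5
#>     rho  p_value n_features n_permutations exact
#>   <dbl>    <dbl>      <int>          <dbl> <lgl>
#> 1     1 0.000198          7           5040 TRUE
```

`autoplot(enc)` draws the seven encoding time courses;
`autoplot(le)` the layer curves. The whole analysis — including decoding,
noise ceilings, group statistics over several simulated subjects, and the
hierarchy test — runs as one reproducible pipeline:

```r
res <- run_pipeline(default_config(seed = 1), out_dir = "run1")
```

which writes `design.csv`, `decoding_timecourse.csv`,
`encoding_timecourses.csv`, `layer_curves.csv`, `noise_ceiling.csv`,
`stats_encoding.csv`, `peaks.csv`, `hierarchy.json`, a YAML copy of the
configuration, and a manifest with per-stage hashes and timings.

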