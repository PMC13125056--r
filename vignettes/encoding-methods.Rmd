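---
title: "Time-resolved linearized encoding of visual features: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved linearized encoding of visual features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eegencode)
```

## The analysis in one paragraph

`eegencode` implements a complete time-resolved linearized encoding analysis
for epoched EEG: ground-truth stimulus annotations (edge maps, surface
reflectance, lighting, world normals, scene depth, body skeleton, action
identity) are turned into predictor matrices, multivariate noise
normalization whitens the channel data, ridge regression models predict the
whitened response at every channel and timepoint from each feature's
predictors, and the resulting per-feature accuracy time courses are analyzed
with resampling statistics. A parallel branch encodes the same features into
layered network-style activations, and the per-feature EEG peak *latencies*
are correlated with the network peak *layers* to quantify the alignment of
the two processing hierarchies. Because real recordings are not required, the
package ships a forward-model generator whose planted structure makes every
stage verifiable: the generator's parameters define a known ground truth that
the pipeline must recover.

## The synthetic experiment

`make_design()` builds a full factorial stimulus set — 20 rooms x 6 actions x
3 characters x 4 camera positions = 1440 scenes — split 1080/180/180 into
train/test/validation. Fifteen rooms are seen only in training; the five
held-out rooms are shared by test and validation but viewed from disjoint
camera pairs, so evaluation always generalizes across rooms and the two
evaluation sets generalize across viewpoints with respect to each other.

`simulate_annotations()` generates per-stimulus feature annotations in the
shape classes of rendering-engine exports: grayscale maps (edges, depth),
RGB maps (reflectance, lighting, normals), a 14x2 joint-coordinate skeleton,
and a one-hot action vector. Continuous features are random linear images of
per-stimulus latent factors plus pixel noise; all features share one latent
factor with weight `rho` (default 0.1), so cross-feature correlation is
present but mild, as in controlled rendered stimulus sets. Maps default to
36 x 27 pixels rather than a photographic resolution: the *shape class* is
what downstream code contracts on, and the reduced size keeps a full
run tractable on one core. Video mode adds 9 frames per stimulus (the frame
count of a 300 ms clip at 30 fps) with small latent jitter per frame.

`simulate_eeg()` is the forward model. Each feature's flattened annotation is
projected to a rank-5 latent signal, mixed into 19 channels, and modulated by
a Gaussian temporal kernel centered on the feature's planted latency
(`tau_ms`) with SD `sigma_ms = 25` ms; kernels are truncated at stimulus
onset so the pre-stimulus window carries noise only. Every trial adds
spatially correlated Gaussian noise with channel covariance
`corr(c, c') = 0.5^|c - c'|` and per-channel SD 3 (single-trial SNR ~ 0.1,
a realistic regime for single-channel evoked EEG). Repetition counts default
to 5 per training stimulus, 30 per test stimulus and 5 per validation
stimulus — 5400/5400/900 trials. Temporal noise is white by default; an AR(1)
option (`ar1_phi`) exists but is off, since evoked-response pipelines rarely
model noise autocorrelation explicitly at 50 Hz.

The planted latencies default to 80 (edges), 120 (reflectance), 160
(lighting), 180 (normals), 200 (depth), 260 (skeleton) and 420 ms (action).
Two considerations fixed these values: they follow the low-to-high ordering
reported for feature processing in visual cortex, and they sit exactly on
the 50 Hz sampling grid (-400..980 ms in 20 ms steps). The second point is a
measurement-theory constraint, not a convenience: a symmetric response kernel
peaking *between* two samples makes the sampled argmax an unresolvable coin
flip between the flanking grid points, so rank-recovery tests would be
testing the noise, not the pipeline. On-grid latencies make "the peak is
recovered" a well-posed claim. Signal amplitudes (default 1 per feature)
were chosen once so that peak encoding accuracies land around 0.6-0.9, below
the upper noise ceiling — comparable in spirit, though deliberately more
favorable in SNR, to published encoding results.

`simulate_layer_activations()` plants the hierarchy's other half: eight
layers labelled "1.0".."4.1" (the residual-block naming of an 18-layer
residual network), each feature contributing through a Gaussian tuning curve
over layer index peaking at its planted layer, plus unit noise.

## Annotation preparation

Following standard practice for linearized encoding, annotations are
flattened (row-major, RGB fastest; fixed purely for reproducibility),
frame-averaged in video mode, and reduced with a centered, unscaled PCA to
100 components for the five high-dimensional features. PCA is fitted on the
training split only and train/validation/test are all projected on those
loadings, so no evaluation information leaks into the predictors (a property
the test suite checks by perturbing a test row and asserting the loadings are
unchanged). Skeleton (28 values) and action (6) keep their native dimensions.
Component signs follow a fixed convention (largest-absolute loading positive)
so stored models are bit-comparable across runs. Rendered maps are not
value-normalized before flattening; PCA centering removes the mean and ridge
regularization absorbs scale.

A Canny edge detector (`canny_edges()`: Gaussian smoothing, Sobel gradients,
non-maximum suppression, two-threshold hysteresis) is provided for deriving
edge annotations from grayscale images, with thresholds expressed relative to
the maximum gradient magnitude (defaults 0.1/0.3, smoothing SD 1 px).

## Multivariate noise normalization

Noise is defined operationally as the deviation of each repetition from its
stimulus' mean response at each timepoint — the assumption being that the
evoked response is constant across repetitions. The per-(stimulus, timepoint)
residuals are pooled and a single Ledoit–Wolf shrinkage covariance is
estimated; with equal repetition counts this equals the average of the
per-cell sample covariances, shrunk once. Shrinking every cell separately
(available as `method = "per_cell"`) is statistically legitimate but, with
only 5 repetitions against 19 channels, each cell's estimate is shrunk
roughly halfway to the identity; the averaged whitener then under-corrects
and leaves substantial residual channel correlation. The pooled default uses
all ~378k residual vectors, shrinks by < 0.1%, and empirically drives the
maximum off-diagonal of the whitened residual covariance below 0.01. The
whitener is the symmetric inverse square root (eigendecomposition with a
relative eigenvalue floor of 1e-12), estimated on the training split and
applied unchanged to all splits.

Whether pre-stimulus timepoints should contribute to the noise estimate is
not obvious — noise-only samples are "purer", but post-stimulus residuals are
what the analysis must whiten. All timepoints are used by default;
`timepoints = "prestim"` restricts to the baseline window.

## Decoding

Pairwise scene decoding measures overall discriminability: for every pair of
test-set scenes and every timepoint, a linear SVM (cost 1, no feature
scaling — the data are already whitened) is trained and evaluated with
stratified 6-fold cross-validation on 6 + 6 pseudotrials (random bins of 5 of
the 30 repetitions, each repetition used exactly once), holding out one
pseudotrial per class per fold. One fold pattern is shared by both classes,
which keeps folds stratified and makes the accuracy exactly invariant under
swapping class labels. The lower triangle of the pairwise accuracy matrix is
averaged into one time course, and the whole procedure is repeated (default
6 times) with fresh random bins. Decoding cost grows with the square of the
scene count; `decode_subject()` accepts stimulus and timepoint subsets, and
the pipeline's default configuration decodes a spread subset of scenes at
every other timepoint.

## Encoding models

For each feature the ridge penalty is selected once per subject: the model is
fitted on the training split at 30 logarithmically spaced penalties from
1e-5 to 1e15, validation responses are predicted, and the penalty maximizing
the Pearson correlation between predicted and observed responses — averaged
over all channels and timepoints — wins (ties to the smaller penalty; an
unpenalized least-squares reference fit is available via `include_ols`).
Responses are repetition-averaged per stimulus within each split before
fitting and evaluation; averaging the 30 test repetitions maximizes the SNR
of the evaluation target and mirrors the noise-ceiling construction. With the
selected penalty the model is refitted on training data and test responses
are predicted; accuracy is the correlation between predicted and observed
responses *across test stimuli*, computed separately in every
(channel, timepoint) cell, then averaged over channels into the feature's
time course. The solver is a single SVD of the centered training predictors,
so the full penalty grid costs one decomposition.

Layer encoding repeats this per (feature, layer) on the PCA scores of the
simulated activations (components retaining >= 90% of training variance). The
layer summary weights each component's test correlation by its explained
variance: `sum(w * r) / sum(w)`, which reduces to the plain mean under equal
weights.

Noise ceilings: per random split, the trials of every stimulus are halved;
stimulus-wise mean responses of the halves are correlated across stimuli per
(channel, timepoint) cell (lower bound), and one half against the mean of all
trials (upper bound); both are averaged over 100 splits. Group responses are
stimulus-wise means — correlating raw trial sequences would mix within- and
between-stimulus variance. Two consequences of this construction are worth
stating because they are easy to get wrong: under pure noise the *upper*
bound does not vanish but converges to sqrt(1/2) (the half's trials are
contained in the all-trials group, so their noise is shared), and a
noise-free predictor can legitimately exceed the *lower* bound (both halves
are noisy where the prediction is not). The test suite asserts exactly these
behaviors rather than the naive ones.

## Inference

All inference is resampling-based. Sign-permutation tests flip each subject's
chance-centered statistic with random signs (10,000 permutations by default)
and use two-tailed rank p-values that include the observed statistic in the
null set, `p = (1 + #{|null| >= |obs|}) / (1 + n_perm)`, so p is never zero.
Condition differences use label-swap permutations preserving group sizes.
Benjamini–Hochberg FDR (via `stats::p.adjust`) corrects across timepoints or
layers at alpha = 0.05. Bootstrap CIs (10,000 resamples, percentile 2.5/97.5)
cover group means, peak latencies, and peak differences; peak-difference
bootstraps resample subjects independently per condition, since image and
video groups are different participants. Peak ties break to the earliest
timepoint / shallowest layer, recorded in the output.

The hierarchy correlation is Spearman's rho between the 7 EEG peak latencies
and 7 network peak layers, with an exact permutation p-value over all
7! = 5040 orderings of the layer vector. The test is one-sided for positive
alignment by default — the scientific hypothesis is that the hierarchies are
aligned, not merely dependent — with a two-sided option
(`alternative = "two.sided"`). Above 8! orderings a seeded Monte-Carlo sample
replaces enumeration and is flagged in the output.

## Orchestration and reproducibility

`default_config()` collects every stage parameter in one YAML-serializable
list; `run_pipeline()` executes simulate → prepare → whiten → decode → encode
(EEG and layers) → noise ceiling → statistics → hierarchy, writing CSV/JSON
results plus a manifest (stage status, wall time, output hashes) and caching
stage outputs so interrupted runs resume. One master seed fans out to named
per-stage substreams (`fan_seed()`): changing the decoding seed can never
perturb the simulation. Identical configurations and seeds reproduce result
tables bit-for-bit, which the test suite asserts by diffing two full runs.

Problem sizes used by the checks: the full default experiment (1440 stimuli,
11,700 trials, 19 channels, 70 timepoints) for whitening, encoding and layer
recovery; ten independent full-scale simulated subjects for latency-rank
recovery; a reduced 6-room design with 8 subjects and 2/4/2 repetitions,
annotation-stimulus assignment shuffled, for the false-positive protection
check; 1000 replicate null simulations (1000 permutations each) for test
calibration. Group-level simulations use 8–15 subjects, representative of
EEG group studies.

## What the synthetic data does and does not establish

The generator emulates the *structure* of a rendered-stimulus EEG experiment:
factorial design with room/viewpoint generalization splits, annotation shape
classes, repetition counts, epoch geometry, spatially correlated sensor
noise, and a planted feature-latency and feature-layer hierarchy. It does not
emulate photorealistic image statistics, eye movements or artifacts, trial-
order effects, nonstationary noise, or nonlinear stimulus-response mappings
— the forward model is exactly linear, which is why near-ceiling encoding
accuracies are attainable. Passing tests therefore establish that the
pipeline is *correct* (it recovers what was planted, at the right rates,
with calibrated error control), not that any particular empirical claim
about cortex holds. On real data, accuracies will sit far lower relative to
the noise ceiling and peak estimates will be correspondingly less stable.

## Known limitations

- Ridge solves use one SVD per (feature, penalty grid); for predictor counts
  far above ~1000 a dual (Gram-space) solver would be preferable.
- The decoding stage is the computational bottleneck (SVM fits scale with
  pairs x timepoints x folds x repeats); full 180-scene decoding at all 70
  timepoints is hours of CPU, which is why subsetting is built in.
- `per_cell` noise-covariance estimation is provided for completeness but
  under-whitens at low repetition counts (see above); use it only with many
  repetitions per stimulus.
- The hierarchy test assumes the 7 features' peak estimates are exchangeable
  under the null; heavy ties in peak layers reduce the effective number of
  distinct permutations.
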