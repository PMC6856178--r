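---
title: "Predicting sperm motility from video representations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting sperm motility from video representations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Manual assessment of sperm motility — the percentages of progressively
motile, non-progressively motile and immotile spermatozoa in a semen
sample — is slow, requires trained personnel and shows substantial
inter-observer variability. `motiliflow` implements an automated
alternative: regression models that map short microscopy video clips of wet
semen preparations (nominally 50 frames/second, 400x magnification)
directly onto the motility triple, treating the three percentages as a
joint multi-output regression target.

The package covers the full experimental pipeline: a synthetic video
simulator with exact ground truth, frame sampling, four video-to-image
representations, a classical texture-feature baseline, CNN regressors with
an optional participant-data fusion head, grouped cross-validation, and a
variance-corrected paired t-test against the ZeroR null model.

## The motility label

A `MotilityLabel` is a triple (progressive, non-progressive, immotile) of
percentages constrained to sum to 100. Models predict the three values
jointly (CNNs) or through three independent scalar regressors (classical
algorithms); in neither case do we renormalise predictions to sum to 100,
because the reference protocol reports the three regressions independently.
Predictions are clipped to [0, 100] because the targets are percentages.

## The synthetic cohort: what it emulates and what it does not

Real motility videos cannot ship with a package, and manual labels are
noisy. The simulator instead provides scenes where ground truth is exact
*by construction*: `nParticles` bright sperm-head-like discs move on a
noisy dark background, each belonging to one of three kinematic classes,

* **progressive** — directed movers: per-frame step of
  `progressiveSpeed` px (default 3) along a persistent heading perturbed
  by Gaussian noise (`progressiveHeadingSigma`, default 0.2 rad), reflected
  at frame borders;
* **non-progressive** — in-place jitterers: an isotropic Gaussian random
  walk (`nonprogJitter`, default 1 px/frame) confined to a disc of
  `nonprogConfineRadius` (default 6 px) around an anchor — motion without
  net progression, the WHO definition of the class;
* **immotile** — static particles with sub-pixel tremor
  (`immotileJitter`, default 0.3 px, i.e. offsets within a 0.15 px disc).

The defaults keep the classes separable in the sense the invariants
require: mean per-frame displacement ordering progressive >
non-progressive > immotile with at least a factor two between consecutive
classes. Class membership counts are apportioned by largest-remainder
rounding of the requested fractions, and the video's label is the realised
particle-count fractions times 100 — not the continuous Dirichlet draw —
so the label is exact for the rendered scene.

Per-video class fractions are drawn from a Dirichlet(2, 1.5, 2)
distribution, giving broad label variation with a slight deficit of
non-progressive mass, qualitatively similar to clinical cohorts.
Participant covariates (age, BMI, abstinence days, log-normal sperm
concentration) are drawn independently of the labels by default; a
`bmiSlope` knob can induce a linear BMI-progressive association for
sensitivity analyses.

What the simulator deliberately does **not** model: flagellar beat
patterns, phase-contrast photometry, debris and non-sperm cells,
hydrodynamic interactions and collisions. Passing tests on synthetic
cohorts therefore demonstrates that the *pipeline machinery* (sampling,
representations, optimisation, evaluation) extracts motion-fraction
information correctly — not that any particular accuracy will transfer to
clinical recordings.

One global seed drives track simulation, rendering noise and covariates
through derived independent streams, so cohorts are bit-reproducible.

## Frame sampling

Two strategies from the reference protocol:

* `sampleFirstMiddle`: the first and middle frame of each of the first 60
  seconds — 120 frames per video — used by the classical baseline. "Middle
  frame" is realised as index `floor(fps/2)` within the second, the only
  natural reading.
* `sampleEvenly`: `n` window start positions linearly interpolated between
  the first frame and the last position where a full window fits, rounded
  half-up. At 7,500 frames, 250 windows of 30 frames tile the video with
  spacing exactly 30; shorter videos produce overlapping windows rather
  than failing. 250 samples per video over 85 videos gives the protocol's
  21,250 training/validation samples.

Indices are 1-based throughout, following R convention.

## Representations

* **Greyscale channel stack**: 30 greyscaled frames stacked channel-wise
  (224 x 224 x 30 at full scale). Greyscale is BT.601 luma
  (0.299/0.587/0.114), rounded back to the 8-bit scale; conversion is
  idempotent.
* **Vertical frame matrix**: each frame greyscaled, resized to 64 x 64,
  flattened row-major to 4,096 values; 30 frames stack into a
  30 x 4096 x 1 image.
* **Sparse optical flow**: Shi-Tomasi/Harris corners detected on the
  window's first frame (quality and minimum-distance constraints), tracked
  with pyramidal Lucas-Kanade over the 30-frame window; surviving tracks
  drawn as 1-px polylines, one fixed palette colour per track, on a black
  canvas. Tracks that fail the solve or leave the frame are dropped, not
  re-seeded — the simplest reading of tracking "over a sequence of 30
  frames". An empty corner set yields a blank canvas with a warning, not
  an error.
* **Dense optical flow**: Farneback polynomial-expansion flow between the
  window's anchor (first) frame and the frame `stride` positions later
  (stride 1 or 10), encoded as an HSV image — hue = flow angle, full
  saturation, value = magnitude normalised by the field's own maximum (an
  all-zero field maps to black). The encoding is the standard flow
  visualisation; per-field normalisation makes the image invariant to
  uniform magnitude scaling.
* **Two-stream inputs**: the raw anchor frame paired with the sparse
  image, the dense image, or their 6-channel channel-wise stack.

The dense flow estimator is implemented in the package (no flow library is
a dependency): quadratic polynomial expansion under a Gaussian
applicability (neighbourhood half-width 5, sigma 1.2), displacement solved
over a Gaussian aggregation window (15 px), 3 iterations per level over a
3-level image pyramid. On 64 x 64 textured images it recovers circular-
shift translations up to 5 px within 0.25 px (median), the package's
translation oracle the test suite asserts. The Lucas-Kanade tracker likewise lives in the package:
2-level pyramid, iterative refinement with replicate-border sampling.

## Tamura features and the classical baseline

The baseline represents each video by 120 sampled frames x an
18-dimensional Tamura texture descriptor = 2,160 features. The descriptor
is coarseness, contrast, and a 16-bin directionality histogram — the only
composition consistent with 2160/120 = 18; line-likeness, regularity and
roughness are therefore not implemented.

* *Coarseness*: per-pixel best window size 2^k (k = 0..5) by maximal
  horizontal/vertical mean differences; ties break toward the smallest k,
  which makes the constant image well-defined (coarseness 1).
* *Contrast*: sigma / kurtosis^(1/4), 0 for constant images.
* *Directionality*: Prewitt gradients; pixels with magnitude >= 12 (8-bit
  scale) vote their edge orientation into 16 bins over [0, pi); an empty
  vote set falls back to the uniform histogram.

Classical regressors run per motility variable behind one registry
(`linear`, `random_forest`, `gaussian_process`, `svr_smo_like`,
`elastic_net`, `random_tree`), delegating to standard implementations
(randomForest, kernlab, e1071, glmnet, rpart); `linear` is a minimum-norm
SVD least squares because the Tamura table has more columns than videos.
Features are standardised on the training fold for the scale-sensitive
algorithms. These choices (and all hyperparameters) are recorded in the
fitted bundle; the reference protocol does not state any of them.

## Deep models and training protocol

Backbones: `tiny` (four stride-2 conv-BN-ReLU blocks; channels w, 2w, 4w,
4w), `resnet18_like` (basic residual blocks, stage plan 2-2-2-2) and
`resnet50_like` (bottleneck blocks, 3-4-6-3), all width-parameterised so
the same code runs at desk scale. After global average pooling the pooled
vector — concatenated with the z-scored participant covariates when the
fusion head is enabled — passes through two fully-connected hidden layers
(2,048 units each in the reference configuration; width is a parameter)
to a 3-unit linear output. There is no output activation; clipping to
[0, 100] happens post-hoc.

Training follows the reference protocol: joint MSE over the three outputs,
Nadam (learning rate 0.002, beta1 0.900, beta2 0.999), early stopping
after 20 epochs without validation improvement, and evaluation of the
checkpoint with the minimum validation MSE rather than the last epoch.
Internally images are scaled to [0, 1] and targets to [0, 1], and the
output bias starts at the training-mean label — purely numerical choices
that speed convergence without changing the optimum. Validation videos are
held out of the training fold *by video*, never by sample. An optional
train-time augmentation (random horizontal/vertical flips and transposes,
off by default) is available for small-sample regimes; motility fractions
are invariant to spatial symmetries, so these are label-preserving, and
`predictModel(tta = TRUE)` averages predictions over the four flip
variants at test time.

Two design details guard the participant-fusion head in small cohorts.
The covariate columns of the first dense layer start at zero, so a fusion
model initially computes exactly what its image-only twin computes. And
because a covariate triple uniquely identifies a training video — letting
an unregularised head memorise labels through it — the whole covariate
vector of a training sample is blanked with probability
`modalityDropout` (default 0.5), the standard multimodal-dropout
regularisation. Both matter only when covariates carry little signal,
which is exactly the regime the synthetic cohorts emulate.

## Evaluation and the corrected t-test

`groupedKFold` shuffles videos and deals them round-robin into k = 3 folds
(85 videos give 29/28/28), so all samples of a video share a fold. The
reference per-fold sample counts (14,166/7,083) imply sample-level
splitting, which would place frames of one video on both sides of a split;
we deliberately deviate and split by video, trading count fidelity for
leakage-free evaluation.

Per-sample predictions aggregate to a per-video triple by unweighted mean;
MAE is reported per variable plus the average. Methods are compared with
the corrected paired t-test on per-fold average-MAE differences:

t = dbar / sqrt((1/J + n_test/n_train) * s_d^2),  df = J - 1, two-sided,

with the n_test/n_train variance inflation (0.5 for 3-fold CV)
compensating for the dependence between folds. Degenerate cases: all-zero
differences give t = 0, p = 1; zero variance with non-zero mean gives
p = 0 with a warning. The test is conservative by design: under a
simulated null (both methods equal plus i.i.d. noise, J = 3), its
rejection rate at alpha = 0.05 stays below the nominal level. No
multiple-testing adjustment is applied across methods, matching the
reference analysis. Two-sided testing is used because the comparisons are
non-directional.

## Problem sizes for the package's own experiments

The reference protocol (85 participants, 224 x 224 inputs, ResNet-50,
250 samples/video) is GPU-scale; the package's self-contained experiments
run the same pipeline at desk scale: 60-video cohorts, 64 x 64 frames,
150-frame videos (3 s of recording; long enough that the 24 sampled
windows of 30 frames per video overlap only moderately), the tiny
backbone (base width 8, 64-unit head, flip/transpose augmentation,
flip-averaged prediction) trained for at most 60 epochs. These sizes
are the package's chosen benchmark conditions; the full-scale
configurations remain available through the same interfaces
(`backboneConfig("resnet50_like")`, `samplingConfig(250, 30)`, 2048-unit
head).

On those synthetic cohorts the expected ordering mirrors the reference
findings: motion-aware representations (dense flow, grey stacks) beat the
ZeroR null model decisively; the single-frame model — which sees particle
count but no motion — cannot, and label-independent participant
covariates change held-out MAE only within noise.

## I/O formats

Videos are read from directories of numbered PNG frames (`readVideo` /
`writeFrameDir`), with an optional `meta.json` carrying the frame rate
(default 50 fps); cohorts serialise to one frame directory per video plus
a VISEM-style CSV (id, progressive, non_progressive, immotile,
concentration, age, bmi, abstinence_days). Container formats (AVI/MP4)
are out of scope for the package itself; recordings should be exported to
frame directories with any standard decoder before analysis.

## Known limitations

* The synthetic scenes are photometrically simple; texture-based features
  (Tamura) face much less texture variation than real phase-contrast
  microscopy, so classical-baseline behaviour on synthetic cohorts is not
  predictive of their behaviour on clinical data.
* The Farneback estimator saturates for displacements beyond roughly a
  quarter of the aggregation window per pyramid level; stride-10 flow on
  fast progressive cells underestimates large displacements (the relative
  ordering of classes survives).
* `pretrained` backbone weights are accepted as a flag for 3-channel
  single-frame models only and are off by default; no weight files ship
  with the package.
* Corner re-detection is not performed mid-window; heavily crossing
  tracks are dropped rather than re-associated (joint probabilistic
  data-association tracking is a non-goal).
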