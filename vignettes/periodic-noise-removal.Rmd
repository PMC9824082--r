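---
title: "Recognising activities from 8x8 thermal frames: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising activities from 8x8 thermal frames: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrirhar)
```

## The problem

Low-resolution infrared (LRIR) arrays such as the Grid-EYE report an 8x8
grid of scene temperatures at up to 10 frames per second. They are cheap,
non-intrusive and privacy-preserving, which makes them attractive for
ambient monitoring of daily activities in care settings: a warm person
appears as a coarse moving blob, rich enough to tell *sit down* from
*walk across* but far too coarse for identification.

`lrirhar` implements a complete analysis pipeline for such data. Frame
streams of varying duration (2-28 s) are equalized to 40 frames, each
frame is flattened row-major into 64 values, and the record becomes a
40x64 *spatiotemporal map* - an image whose rows are time and whose
columns are pixels. All handcrafted feature extraction and the package's
periodic-noise removal operate on these maps; a sequence model (a compact
CNN-LSTM) works on the raw 40x8x8 frame streams instead.

## Frame equalization

Records longer than 40 frames are thinned at regular index intervals:
frame `i` of the output takes input index `i*(L-1)/(T-1)`, rounded with
half-integers going to the earlier frame, so both endpoints are always
kept. Shorter records grow by repeatedly inserting, at the widest
remaining gap (leftmost on ties), a frame equal to the element-wise mean
of its two neighbours. Index-based (not wall-clock) spacing is used; the
operation is idempotent, and thinning never invents new pixel values.

## Periodic noise and its removal

Spatiotemporal maps from these sensors show axis-aligned periodic noise:
*vertical* stripes from pixels that keep an identical value across all 40
frames (never occluded by a subject), and *horizontal* stripes from runs
of near-identical consecutive frames (slow movement or stillness).
Axis-aligned periodic structure concentrates on the two central lines of
the shifted 2D Fourier power spectrum. The package stores spectra with
the zero-frequency (DC) coefficient at row 21, column 33 of the 40x64
array; the *horizontal stripe* is that row (31 symmetric pairs about DC)
and the *vertical stripe* that column (19 pairs). Peaks on the horizontal
stripe encode vertical image noise and vice versa.

Removal proceeds per image:

1. compute the log power spectrum `log(1 + |F|)` (the +1 keeps exact
   zeros finite; any monotone variant only shifts thresholds);
2. on each stripe, compute the mean and standard deviation of the non-DC
   cells and a threshold `T = mu + i1 * 0.5 * sigma`;
3. pair each cell with its mirror about DC, score pairs by their mean
   log power, and take the pairs above `T`;
4. rescale the top `Num` pairs so their log magnitude equals the stripe
   mean, preserving the complex phase and applying the same change to
   both mirror members (this keeps the spectrum Hermitian, hence the
   inverse real);
5. invert the modified spectrum.

DC is never touched, so the map mean is preserved exactly. The integer
grid index `i1` (default grid -2..8) and the pair counts
(`Num` up to 31 horizontal / 19 vertical) are *learned*: a stratified
K-fold cross-validation (K = 10) denoises the training images for every
candidate cell, fits a downstream classifier, and keeps the cell with the
highest fold-averaged validation accuracy. Thresholds are always
per-image - the stripe statistics of one map say nothing about another -
while `i1` and the counts are global.

Three design points deserve emphasis:

* **Feasibility.** Pairs above a threshold form a prefix of the
  value-sorted pair list, so the candidate denoising depends only on the
  count; the threshold index acts through a feasibility mask (a cell is
  feasible only when every training image has at least `Num` pairs above
  its own threshold). Infeasible cells are excluded from fold averaging.
  Ties resolve toward fewer suppressed pairs, then the higher threshold.
* **Joint suppression.** The two stripes are disjoint coefficient sets.
  Averaging two separately inverted images in which each stripe is
  suppressed alone would leave every peak halfway between its original
  value and the stripe mean - a formulation under which no parameter
  setting can remove more than 75% of a stripe's energy. The package
  therefore applies both suppressions to one spectrum before a single
  inversion, which is what the merge reduces to when each
  direction-specific image fully suppresses its stripe, and which meets
  the >= 90% energy-reduction behaviour a working stripe filter should
  show.
* **Search scorer.** During the grid search the default scorer is a
  linear discriminant on the leading 45-dimensional SVD subspace of the
  denoised training fold (`scorer_svd_linear`); a multinomial
  logistic-regression scorer (`scorer_svd_lr`), matching the pipeline's
  final classifier, is provided and pluggable. The discriminant is used
  by default because the search evaluates hundreds of (fold, cell)
  combinations and the two scorers rank cells almost identically on this
  feature scale.

Because thresholds are recomputed per image, denoising is not idempotent
on the whole map - a second pass may suppress the next-ranked pairs. It
*is* contractive on the noise it removed: coefficients already pulled to
the stripe mean are no longer peaks, so a second pass barely moves them.

## Feature extraction

Four extractors map a (denoised) 40x64 map to a feature vector:

* **SVD subspace** (default k = 45): flattened maps are mean-centered and
  projected onto the leading right singular vectors of the training
  matrix. k = 45 captures well over 95% of variance on datasets of this
  kind; test data are centered with the training mean.
* **Fisher canonical variables**: up to Q-1 components (14 for the
  15-class problem) of the generalized eigenproblem of between-class
  versus within-class scatter. With 2560 variables and tens of samples
  per class the within-class scatter is singular, so it is
  ridge-regularized with `lambda = ridge * tr(Sw)/r` (default
  `ridge = 1e-3`); the eigenproblem is solved in the orthonormal basis
  spanning the centered training data, which is exactly equivalent to the
  full 2560-dimensional problem because both scatter matrices vanish on
  the orthogonal complement of that span.
* **Block 2D-DCT** (240 values): the map is tiled into 40 non-overlapping
  8x8 patches (5 time-blocks x 8 pixel-blocks, row-major order); each
  patch gets an orthonormal type-II DCT and contributes its first 6 JPEG
  zigzag coefficients, DC first. Adding a constant to the map moves only
  the per-patch DC slots.
* **GLCM texture** (120 values): the map is quantized to 8 gray levels by
  per-map min-max scaling and split into five 8x64 time-patches; for each
  patch x distance {1, 3} x angle {0, 45, 90} degrees a symmetric,
  normalized co-occurrence matrix yields correlation, contrast,
  dissimilarity and energy. Angle conventions: 0 degrees steps along the
  64-pixel axis, 90 degrees along the time axis, 45 degrees one step
  along each. A constant map quantizes to one level; its correlation is
  defined as 0.

## Classifiers and evaluation protocol

The classifier bank holds a linear-kernel SVM (cost 1), a random forest
of 100 trees, 1-nearest-neighbour, and multinomial logistic regression
fitted by a quasi-Newton (BFGS-family) optimizer, each behind one train /
predict interface with seeded determinism; `cv_select()` compares
specifications by stratified 10-fold cross-validation. Experiments use
repeated stratified 75/25 holdout (default 10 repeats) with the denoiser
and any subspace extractor fitted on the training portion only. The
noise-removal A/B harness runs the identical splits with denoising off
and on; cross-layout transfer fits on one layout and scores on the other
(harmonizing the AS/AL label prefixes); the sensor-subset harness
extracts features per sensor and concatenates them.

The denoiser is refit on every repeat's training portion by default,
matching the train-only contract of the learning algorithm. A
`denoise_refit = "once"` option fits on the first repeat's training
portion and reuses the parameters - a speed profile that slightly relaxes
the per-repeat independence of the arms and is therefore off by default.

## The CNN-LSTM

The sequence model applies three 3x3 convolutions (16, 32, 32 filters,
same padding, ReLU, no pooling - the frames are only 8x8) identically to
each of the 40 frames, feeds the flattened per-frame features to two
stacked 32-unit LSTM layers, and reads a softmax over activities from the
final hidden state. Inputs are standardized with the training-set mean
and standard deviation. Training uses Adam (1e-3) on the cross-entropy
loss with batch size 32; the study-scale budget is 1000 epochs, and the
epoch count is freely reducible for desk-scale runs. The implementation
is a small, self-contained network written directly in R (dense matrix
algebra, backpropagation through time), with gradients verified against
finite differences in the test suite; with all seeds fixed, training and
evaluation are reproducible on one CPU.

## The synthetic scene simulator

The simulator exists so that every stage is testable without the
deposited recordings. It emulates the acquisition design: 10 fps, record
durations uniform on 2-28 s, ambient background drifting 18 to 21 degC
across a session, 0.25 degC sensor quantization, 0.1 degC per-frame pixel
noise (the effective noise floor of these arrays is dominated by the
quantization step), and three viewpoints - two side sensors and one front
sensor around a unit activity area.

Subjects are anisotropic Gaussian temperature bumps (~10 degC over
ambient at close range) with a perspective model: the activity area is
about 1.5 m deep and the sensor sits 1.5 m (small layout) or 2.5 m
(large layout) from its center, so a subject at depth `d` is
`dist = sensor_dist - 0.75 + 1.5 d` metres away; apparent body size
scales with `1/dist` and the measured temperature bump with the
solid-angle fraction `(1.5/dist)^2`, capped where the body fills a whole
pixel. The wider field of view at distance also compresses apparent
positions toward the image center. These three distance effects are what
make the close-range layout genuinely more informative and depth-axis
motion visible to a sensor looking along it.

Activity scripts are minimal kinematic sketches: postural transitions
(sit, stand, fall) are timed within the record, while locomotion advances
at natural pace - one scene crossing per ~5 s, turning at the ends - so a
long record holds several crossings rather than one slowed-down one.
Participant identity modulates body size, pace and clothing warmth. The
scripts' only contract is class separability and a plausible motion-energy
ordering; they are not biomechanical models, they contain no occlusion
physics, and nothing in them reproduces the radiometric detail of a real
scene. Passing tests on simulated data therefore demonstrate that the
algorithms behave as specified under the documented statistical
structure, not that any particular accuracy carries over to real
recordings.

Periodic noise is injected additively in the map domain as sinusoidal
stripes on the central-stripe frequency bins. The canonical noisy
condition draws, per record, 2-3 vertical components (3-28 cycles) and
1-2 horizontal components (2-17 cycles) with amplitudes uniform on
1.0-2.5 degC and random phases - mirroring the fact that *which* pixels
stay unchanged differs from record to record. A fixed-footprint injection
is available for spectral oracle tests. Clean maps are retained alongside
so tests can measure recovery exactly.

## Problem sizes and numerical choices

The test suite and the bundled experiments run at desk scale, chosen as
the package's own defaults: the full two-layout factory (480 + 210
records), the 15-class noisy benchmark of 450 records with ten 75/25
repeats, 72-record fixtures for unit tests, and reduced CNN-LSTM
configurations (4/8/8 filters, 12-unit LSTMs, tens of epochs) for the
overfit and gradient checks. Numerical contracts asserted in the tests:
transform round-trip to 1e-9, map-mean preservation under suppression to
1e-6, orthonormal bases to 1e-9, and analytic-versus-numerical gradient
agreement to 1e-4.

## Known limitations

* The denoiser assumes single-line central stripes; band-like periodic
  noise spread over adjacent lines is out of scope.
* The suppression replaces peak magnitudes but keeps the (noise-dominated)
  phase; residual energy at the stripe-mean level remains.
* Fisher canonical variables with ~22 training samples per class in 2560
  dimensions depend on the ridge choice; the default is a scale-relative
  heuristic, not an optimized value.
* The simulator's blobs carry no posture detail beyond height and extent,
  so feature rankings measured on it (e.g. how much better SVD does than
  GLCM) should not be read as predictions for real sensors.
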