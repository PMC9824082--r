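# lrirhar

Human activity recognition from **low-resolution infrared (LRIR) frame
streams** — the 8×8 thermal images produced by Grid-EYE-class thermopile
arrays used for privacy-preserving monitoring of daily activities in
healthcare settings.

A person in front of such a sensor is a coarse warm blob: enough to
distinguish *sit down*, *stand up*, *walk across*, or two people moving,
but far too coarse to identify anyone. `lrirhar` implements a complete
pipeline for this data, whose centerpiece is a **supervised periodic-noise
removal algorithm in the 2D Fourier domain**.

## The method

Each record is equalized to 40 frames and vectorized into a 40×64
*spatiotemporal map* `X` (rows = time, columns = row-major pixels), treated
as an image. Maps show axis-aligned periodic noise — vertical stripes from
pixels that never change, horizontal stripes from near-identical
consecutive frames — which concentrates as symmetric peak pairs on the two
central lines of the shifted power spectrum

```
F[u,v] = Σ_m Σ_n X[m,n] e^{-j2π(um/M + vn/N)},   P = log(1 + |F|),
```

with DC at (row 21, column 33) of the 40×64 spectrum. On each central
stripe, a per-image threshold

```
T = μ + i1 · 0.5 · σ
```

(μ, σ = stripe mean and standard deviation of `P`, DC excluded) selects
candidate peak pairs; the top `Num` pairs are rescaled so their log
magnitude equals the stripe mean (phase and Hermitian symmetry preserved,
DC untouched), and the spectrum is inverted. The integer `i1` (grid −2…8)
and the pair counts `Num_h`/`Num_v` are learned by stratified 10-fold
cross-validation against downstream classification accuracy, with
infeasible (threshold, count) cells masked.

Around that core the package provides:

* four feature extractors — SVD subspace projection (k = 45), Fisher
  canonical variables (≤ Q−1 components, ridge-regularized), block 2D-DCT
  zigzag coefficients (240), patchwise GLCM texture statistics (120);
* a classifier bank — linear SVM, random forest (100 trees), 1-NN, and
  multinomial logistic regression (quasi-Newton optimizer) — with
  stratified 10-fold model selection;
* a compact CNN-LSTM sequence model (3×3 convolutions with 16/32/32
  filters applied per frame, two 32-unit LSTM layers, softmax head),
  implemented from scratch in R with verified gradients;
* a synthetic thermal-scene simulator reproducing the study design
  (3 participants × 8 single-subject activities × 10 repeats × 2 sensor
  layouts, plus 3 pairs × 7 double-subject activities × 10 repeats, and a
  9-participant × 9-activity × 3-repeat single-layout design) with
  controllable stripe-noise injection;
* an experiment harness — repeated stratified 75/25 holdout,
  noise-removal A/B comparison, cross-layout transfer, sensor-subset
  selection — and pairwise-interpolation augmentation (10 maps per
  (subject, activity) group → 20).

## Worked example

Simulate the large-layout 15-class dataset (450 records), inject
record-varying stripe noise, and compare SVD + logistic-regression
accuracy with and without the learned denoiser on ten matched 75/25
splits (about a minute on one CPU):

```r
library(lrirhar)

records <- build_coventry_like(scene_config(), seed = 42, sensors = "S1")
large   <- Filter(function(r) r$layout == "large", records)
data    <- build_dataset(large, "S1")
data
#> <dataset_tensor> 450 maps of 40 x 64 | 15 classes | sensor S1

noisy <- inject_dataset_noise(data, seed = 42)
ab <- ab_noise_test(noisy, extractor = "svd",
                    classifier = classifier_spec("lr"),
                    denoise_refit = "once", repeats = 10, seed = 42)
ab$off
#> <experiment_result> test accuracy 22.32% +/- 2.73% over 10 repeat(s)
ab$on
#> <experiment_result> test accuracy 81.16% +/- 1.99% over 10 repeat(s)
ab$on$config$denoise_params
#> <noise_params> horizontal stripe: i1* = 2 , Num* = 4 | vertical stripe: i1* = 0 , Num* = 2
```

The record-varying stripe noise cripples the subspace features (22%
accuracy on 15 classes); the learned suppression recovers most of the
clean-data performance (+58.8 points). The fitted parameters say: on the
central horizontal stripe, suppress the 4 highest peak pairs above
`μ + 1.0σ` of each image's own stripe statistics; on the vertical stripe,
the 2 highest pairs above `μ`.

Fitted parameters can be saved and reused (`write_noise_params()` /
`read_noise_params()`), and a thin command-line wrapper with
`simulate` / `denoise-fit` / `ab-test` subcommands is installed under
`inst/cli/lrir-har.R`.

## Package layout

| Area | Files |
|---|---|
| Frame-stream I/O, manifests | `R/io_frames.R` |
| Equalization, vectorization | `R/preprocess.R` |
| Fourier-domain denoising | `R/denoise.R` |
| Feature extractors | `R/features.R` |
| Classifier bank | `R/classify.R` |
| CNN-LSTM | `R/deep_model.R` |
| Scene simulator, noise injection | `R/synthetic_data.R` |
| Augmentation, experiment harness | `R/augment_eval.R` |
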