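---
title: "Texture-based EUS lesion classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based EUS lesion classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eustex)
```

`eustex` classifies endoscopic-ultrasound still images of pancreatic
lesions into pancreatic cancer (PC, the positive class, label 1) and
chronic pancreatitis (CP, label 0) from second-order texture statistics of
a rectangular sub-image of the lesion. This vignette is the package's own
account of each stage: the model, its assumptions, the tunable parameters
and their defaults, and the choices made where the design was genuinely
open.

## From image to sub-image

Images are 8-bit grayscale matrices (BMP as saved by the echoendoscope, or
PNG). RGB containers are accepted only if all three channels are
identical; any genuine colour content (e.g. a Doppler or annotation
overlay) is rejected rather than silently flattened, since an overlay
would contaminate the texture statistics.

The lesion boundary arrives as a polygon — a plain-text file of `row,col`
vertices, **0-based**, closed implicitly. The polygon must be simple, have
at least three vertices, and lie inside the image. Rasterization uses the
even-odd rule on pixel centers, with centers exactly on the boundary
counted as inside; this makes a rectangle with corners (2,3) and (17,40)
cover exactly rows 2–17 and columns 3–40, which is what a reader of the
vertex file expects.

Texture statistics assume (approximate) stationarity, so the analysed
region must be a solid rectangle rather than an arbitrary blob: the
package crops the **maximum-area axis-aligned rectangle** inside the
rasterized mask. The search is the standard dynamic-programming
histogram-of-heights scan, which enumerates every maximal rectangle once;
ties are broken deterministically (larger height, then smaller origin row,
then smaller origin column), so the same ROI always yields the same crop.
Rectangles smaller than 8×8 are refused — below that the 3-level wavelet
decomposition and the distance-2 co-occurrence statistics become
degenerate.

All matrix-based features operate on a quantized copy of the sub-image:
min–max linear binning of the sub-image's own intensity range into
**G = 64** levels (bin indices 0…63; a constant image maps to bin 0). G is
a compromise: too few levels blur the co-occurrence structure, too many
make the G×G matrices sparse at typical sub-image sizes (a 64×64 crop
fills a 64×64 matrix with ≈ 8k pairs per direction). Because the binning
is per-sub-image min–max, matrix features are invariant to affine
intensity rescaling of the crop; absolute brightness information is
carried by the histogram and gradient categories instead, which act on
raw intensities.

## The 105-feature inventory

The canonical inventory (`feature_inventory()`) has 9 categories and a
fixed column order:

| category | n | contents |
|---|---|---|
| `histogram` | 10 | population moments of raw intensities (mean, variance, SD, skewness, excess kurtosis), energy and entropy of the 256-bin normalized histogram, range, 10th/90th percentiles |
| `glcm` | 32 | 16 Haralick statistics × distances {1, 2} |
| `glrlm` | 11 | run-length statistics, 4 directions averaged |
| `glds` | 5 | grey-level difference statistics, 4 unit displacements pooled |
| `wavelet_entropy` | 10 | Shannon entropy of normalized coefficient energy, per subband |
| `wavelet_std` | 10 | coefficient SD per subband |
| `wavelet_energy` | 10 | mean squared coefficient per subband |
| `laws` | 9 | mean absolute response of the 3×3 Laws masks, L3L3-normalized |
| `gradient` | 8 | Sobel magnitude statistics |

Conventions applied uniformly: logarithms are base 2 with 0·log 0 := 0;
moments are population moments (divide by *n*); skewness and excess
kurtosis of a zero-variance sample are defined as 0. Under these rules a
constant sub-image produces a fully finite vector (zero entropies, zero
contrasts, histogram energy 1), which the tests assert.

The clinical literature on this pipeline names its selected statistics in
translated terminology; the package maps them to standard Haralick
nomenclature: *consistency* = angular second moment (and histogram
energy), *invariant moment* = inverse difference moment (homogeneity),
*absolute value* = dissimilarity, *variance of differences* / *entropy
differences* = difference variance / difference entropy. The 16-feature
reference subset under this mapping is exported as
`reference_selected_features()` — nine distance-1 co-occurrence
statistics, three histogram statistics, the wavelet entropies of `cv1` and
`cv2`, the wavelet SD of `ca3`, and the grey-level difference variance —
16 features from 5 categories.

Co-occurrence details that differ between published variants and had to be
fixed here: grey levels enter the formulas 0-based; each directional count
matrix is symmetrized (transpose added) and normalized before the four
directions (0°, 45°, 90°, 135°) are averaged; *sum variance* is taken
about the sum average (the historical definition about the sum entropy is
widely regarded as a typographical accident); *correlation* is defined as
0 when a marginal is degenerate; IMC1 is 0 when the marginal entropy
vanishes; IMC2's radicand is clamped at 0. Run-length statistics are
computed per direction and averaged at the feature level, with grey level
g entering the low/high-grey-level emphases as g + 1 so level 0 has a
finite weight. The Laws features are normalized by the L3L3 response,
removing illumination; `laws_l3l3` is therefore identically 1 and retained
as the category's reference entry (it carries no class information and is
flagged as constant by the scaler).

## Wavelet stage

The 2-D discrete wavelet transform uses **Daubechies-4** (8 taps) with
**half-point symmetric** boundary extension, iterated 3 times on the
approximation band: subbands `ch1…cd3` plus `ca3`, where `ch` is the
horizontal-detail band (lowpass along width, highpass along height), `cv`
vertical and `cd` diagonal. The filter bank is implemented in the package
(analysis, synthesis, and the 2-D separable wrappers); with symmetric
extension each level stores ⌊(n + 7)/2⌋ coefficients per axis — slightly
redundant, which is what makes the inverse exact. `wavelet_reconstruct()`
reproduces the input to ~1e-12; the test suite also pins level-1
coefficients of a fixed 8×8 fixture to values computed with an independent
separable db4 implementation. The subband entropy uses the normalized
coefficient-energy distribution \(q_k = c_k^2/\sum c^2\),
\(H = -\sum q_k \log_2 q_k\), so n equal-magnitude coefficients give
exactly \(\log_2 n\) bits and an all-zero subband is defined to 0.

## Feature selection

**Stage 1 — class distance.** Each feature is scored
\[ d_j = \frac{|\mathrm{med}(x_{j,PC}) - \mathrm{med}(x_{j,CP})|}
{\mathrm{MAD}_{PC} + \mathrm{MAD}_{CP} + \varepsilon},
\qquad \varepsilon = 10^{-12}, \]
with the MAD unscaled (no 1.4826 consistency factor) and taken about the
class median. The median gap is the classical criterion for this pipeline;
the MAD normalization is this package's operationalization — the 105
features live on wildly different scales (probabilities, intensity units,
bits), and a raw median gap would rank by unit size rather than by
separation. The score is symmetric, translation- and scale-invariant, and
0 exactly when the medians coincide. Ties (e.g. many features scoring 0 on
a null cohort) break by canonical inventory order, so rankings are
deterministic and row-order invariant. The top **m = 25** features form
the preliminary pool.

**Stage 2 — sequential forward selection.** The default mode is
*ranked-incremental*: the pool features are added strictly in ranking
order and each prefix's CCR is measured; this matches the way the
CCR-versus-k curve is classically reported (k runs 1…25, the set at step k
contains the set at step k − 1), and its optimum is the smallest k
attaining the maximal CCR. A *greedy* mode (each step adds the candidate
maximizing CCR) is available behind `mode = "greedy"` for comparison. CCR
is evaluated with the same repeated stratified half-and-half protocol as
the final validation, with its own seed.

**Selection optimism.** Both stages see the full cohort, and the final
validation then reuses the same cases: this mirrors the classical protocol
faithfully, but it leaks information — the reported CCR of a subset
selected on the same data is biased upward. The package keeps the
protocol as the default because reproducing it is the point, and exposes
the ingredients (`stratified_half_split()`, `fit_scaler()`, `train_svm()`)
for a nested selection-inside-training analysis. The acceptance analysis
quantifies the effect from the other side: on a *null* cohort (identical
class parameters) the half-and-half accuracy of an a-priori fixed subset
stays at 50 ± a few points, whereas a subset re-selected on the same null
table scores well above chance (≈ 60–70% at n = 60) purely through chance
correlations. Any fixed-subset evaluation in the tests therefore uses
`reference_selected_features()`.

## Classifier

A binary SVM (libsvm via **e1071**). Defaults: RBF kernel, **C = 1**,
**γ = 1/k** for k features, no class weights — chosen for reproducibility,
with z-scoring making the conventional γ meaningful. The scaler is fitted
on training rows only (center = mean, scale = population SD; constant
features get scale 1 and are flagged) and applied unchanged to test rows.
An optional inner 5-fold grid search (`svm_config(tune = TRUE)`) sweeps
C ∈ 2^{−5…15}, γ ∈ 2^{−15…3} in powers of 4 with deterministic stratified
folds. Prediction goes through the decision values so that the knife-edge
case (decision value exactly 0) resolves deterministically to CP — the
class whose follow-up pathway (surveillance rather than resection) makes
the conservative default. Class imbalance (the reference roster is 262 PC
vs 126 CP) is deliberately not reweighted by default, matching the
classical protocol; `svm_config(class_weights = ...)` exists.

## Validation

**Repeated stratified half-and-half.** Each of `n_trials` (default 200)
trials draws a fresh uniform stratified split — ⌊n/2⌋ of each class to
training (so 262 PC/126 CP always gives 131 + 63 = 194 per side) — fits
scaler and SVM on the training half, predicts the other half, and computes
accuracy, sensitivity, specificity, PPV and NPV in percent (PC positive).
Metrics are averaged **per trial**, and the standard error is the
across-trial sample SD divided by √n_trials. Per-trial averaging is why a
reported mean PPV cannot be re-derived from mean sensitivity/specificity
and prevalence: the ratio of means is not the mean of ratios. A trial with
a zero denominator (e.g. no positive calls) yields an undefined metric,
which is excluded from that metric's average and counted in the report.
The per-trial identity accuracy = sensitivity·π + specificity·(1 − π),
with π the test-half prevalence, holds exactly and is asserted in the
tests.

**Leave-one-out.** Every case is tested once against a model (with its own
scaler) trained on the rest; the N predictions pool into a single
confusion matrix, giving one deterministic metric set with SE 0. On a
separable cohort the two protocols agree closely — the classical "mutual
support" argument — and the acceptance checks assert agreement within 5
points.

## The synthetic cohort generator

Clinical EUS images are not distributable with the package, so the
generator stands in. It emulates the dominant statistical structure of
B-mode speckle: the magnitude of a complex circular-Gaussian field —
white noise smoothed by a Gaussian kernel of width `correlation_length` —
has Rayleigh-like amplitude statistics and a controllable grain size. The
field is rescaled so its mean equals `echogenicity`, bright Gaussian blobs
(σ = 1.5 px) are added at Poisson rate `focus_rate` per 1000 px² with peak
`focus_amplitude` (emulating hyperechoic foci such as the calcifications
of chronic pancreatitis), independent Gaussian noise of SD `noise_sigma`
is added, and the result is clipped to [0, 255] and rounded. Smoothing is
circular (FFT on the torus), so any correlation length is well defined.
Everything is driven by a seed; cohort images derive per-image seeds from
the master seed by a fixed integer hash, so cohorts reproduce across
platforms.

The default class conditions — PC: correlation length 6 px, echogenicity
90, focus rate 0.2; CP: correlation length 2 px, echogenicity 115, focus
rate 1.5, both with noise SD 8 — encode the qualitative clinical contrast
(a coarser, hypoechoic malignant mass versus finer, brighter,
calcification-rich inflammatory tissue) at class separations chosen once
as the package's study conditions. What the generator does **not**
emulate: depth-dependent attenuation and focusing, acoustic shadowing
behind calcifications, log-compression curves of specific scanners,
anatomical context, or operator variability. Synthetic classes separated
in second-order statistics are therefore much easier than clinical
material — the near-perfect accuracies on the separable cohort validate
the pipeline's mechanics (features respond to the knobs they should,
selection finds them, the classifier and protocols are wired correctly),
and say nothing about clinical diagnostic performance.

Problem sizes used by the tests and the acceptance analysis, chosen as the
package's standard desk-scale conditions: separable and null cohorts of
60 + 60 images at 64×64; SFS scored with 10 trials per prefix during
selection; 20 validation trials (separable) and 50 (null); oracle
comparisons on 50 random 8×8 fixtures.

## Numerical choices and degenerate inputs

* ε = 10⁻¹² in the class distance guards the zero-spread case (two
  constant classes with different medians score ~10¹² rather than ∞).
* `curve_optimum()` takes the smallest k on CCR ties; greedy SFS breaks
  candidate ties toward the better-ranked feature; the grid search takes
  the first (smallest C, then γ) maximum.
* Constant images: every feature finite by the degenerate rules above;
  constant features: scale 1 and flagged, so they pass through the SVM as
  exact zeros after centering.
* The BMP reader supports the uncompressed 8-bit palette and 24-bit forms
  (bottom-up or top-down), verifying that palette or channels are truly
  grayscale; the writer emits standard 8-bit palette BMP.
* Wavelet reconstruction error is asserted below 10⁻⁸ (observed ~10⁻¹²);
  feature-oracle agreement below 10⁻¹⁰ (observed 0 to ~10⁻¹⁴).

## Known limitations

* The default protocol reproduces the classical all-data feature
  selection, with the optimism documented above; nested selection is left
  to the caller by design.
* Sub-image extraction takes one rectangle per ROI; lesions with extreme
  aspect ratios or concavities lose area, and no multi-rectangle tiling is
  attempted.
* The 105-feature inventory is fixed; there is no interface for extending
  categories without changing the canonical order.
* No probability calibration or ROC analysis: the classifier reports hard
  labels, and the metric set is the classical five.
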