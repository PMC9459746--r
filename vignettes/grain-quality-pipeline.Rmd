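---
title: "Methods: image descriptors, PCA reduction and neural classification of barley grain quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image descriptors, PCA reduction and neural classification of barley grain quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainscan)
```

## The problem and the modelling approach

Quality grading of malting barley asks, for every kernel, a two-state
question: is the grain *good*, or is it *damaged* (mold-infected, broken in
half, dehulled, darkened at the tips)? grainscan answers it from bench
images in four stages:

1. each kernel is isolated as a binary mask plus RGB crop;
2. a fixed bank of 64 graphic descriptors is computed per kernel —
   geometry, classical shape coefficients, per-channel colour statistics,
   and texture;
3. the descriptor space is compressed by principal component analysis
   (PCA), because 64 correlated inputs are far too many for the small
   training sets typical of grain studies and inflate classifier size;
4. an `n-h-1` multilayer perceptron maps the retained components to a
   good/damaged probability.

The package also ships a synthetic grain-image generator with known ground
truth; every stage is validated against it and against analytic shapes and
brute-force oracles.

## The synthetic generator: what it emulates, what it does not

`render_dataset()` draws kernels as rotated filled ellipses in the
yellow-tan colour range on a dark uniform background. The rendered
features are chosen so that no descriptor block is degenerate:

* **size fractions** `F22`/`F25`/`F28` set the nominal semi-minor axis to
  11 / 12.5 / 14 px — the 2.2 / 2.5 / 2.8 mm sieve width classes at an
  assumed working resolution of about 10 px/mm (the original imaging
  geometry is unpublished, so the scale is a package convention, jittered
  per grain with sd 0.8 px);
* **elongation** is drawn uniformly in 2.0–2.6, the typical length:width
  ratio of barley kernels;
* **shading** combines a lengthwise brightness profile and a darker
  crease along the major axis, giving non-trivial gradient and
  co-occurrence statistics; per-pixel Gaussian noise (default sd 2 grey
  levels) does the same for run lengths;
* **damage modes** render the four visually distinctive defect classes:
  `mold` (multiplicative dark patches), `half` (ellipse clipped by a chord
  through the centre), `dehulled` (brighter, noise-free patch of exposed
  endosperm), `dark_ends` (darkened caps beyond 72% of the semi-major
  axis). Defect classes without a describable visual signature (sprouted
  grain, pest damage, foreign seeds) are deliberately not modelled.

The generator makes no attempt at photorealism: there is no perspective,
no specular reflection, no husk texture, no touching grains. Passing
tests on synthetic data therefore demonstrate the *correctness of the
computational chain* — segmentation recovery, descriptor definitions,
spectral identities, training dynamics — not field-ready accuracy on real
bench images, whose defect contrast is subtler.

All randomness flows from one integer seed; two renders of the same
configuration are byte-identical, and the class assignment is the first
draw from the stream so tests can replay it independently.

## Segmentation

No segmentation algorithm is prescribed for this kind of bench imagery,
so the package uses the standard parameter-light chain: luminance
conversion, Otsu threshold (foreground polarity auto-detected by
comparing the border median to the threshold), 8-connected component
labelling, hole filling, and an area filter (default `min_area = 50` px —
about a quarter of the smallest plausible kernel at the working
resolution, small enough to keep grain halves). Regions are reported
row-major by centroid with 0-based, half-open crop windows, so region
order and offsets are reproducible to the pixel. Touching kernels are not
split; the generator's sheet mode guarantees non-overlap, and single-grain
images are the default.

## The 64-descriptor bank

`canonical_descriptors()` freezes the names and order: 12 geometric + 8
shape + 30 colour + 14 texture. Conventions that required a decision:

* **Contour length.** `Circumference` is the 8-connected contour length
  (Moore tracing) with diagonal steps weighted by √2 and Kulpa's 0.948
  correction. The uncorrected chain length overestimates a smooth
  perimeter by about 5%, which would bias every P-dependent shape factor
  (a raw-chain disk scores ≈ 0.91 on the 4πS/P² circularity instead
  of ≈ 1.02).
* **The geometric block nominally holds 13 quantities.** The fitted
  ellipse area `Ellipse` equals `π/4 · MajorAxisLength · MinorAxisLength`
  exactly, so it is returned by `compute_geometric()` but excluded from
  the canonical 64-name record; excluding a strictly redundant quantity
  keeps the bank at 64 informative descriptors.
* **`OAR`** is read as object-area-to-bounding-box ratio and **`Circle
  diameter`** as the equal-area circle diameter `2√(S/π)`.
* **Moment ellipse.** Axes follow the regionprops convention
  (`4√λ` of the pixel-coordinate covariance eigenvalues); eccentricity is
  `√(1 − λ₂/λ₁)`.
* **Feret ratio** scans rotations at a 1° step over boundary pixel
  centres.
* **HSV.** Hue is treated linearly on [0, 1] (no circular statistics) and
  achromatic pixels get hue 0; saturation and value are on [0, 1], RGB on
  0–255. `STD` is the population standard deviation throughout.
* **Texture.** Luminance is min–max quantized to 8 grey levels over the
  foreground. The co-occurrence matrix is symmetric, distance 1, averaged
  over the 0°/45°/90°/135° directions, with pairs counted only when both
  pixels are foreground. Run-length features are computed per direction
  and averaged; `rFIR` is read as run percentage (runs per foreground
  pixel). Gradients are Sobel responses normalized by 8 (grey levels per
  pixel), evaluated on the foreground eroded by one pixel so every
  window lies inside the object.
* **Degenerate cases are fixed conventions, not errors:** constant
  foreground quantizes to level 0; a single-level co-occurrence field has
  correlation 1; zero gradient variance gives skewness = kurtosis = 0; a
  vanishing boundary-distance spread returns the Haralick sentinel `1e6`.
  Empty masks and too-small foregrounds raise typed errors.

Every colour and texture feature, and all eight shape coefficients, are
checked against independent explicit-loop oracles in the test suite; the
geometric block is checked against closed forms on rasterized disks,
squares and ellipses.

## Principal component reduction

`fit_pca()` standardizes by default (correlation-matrix PCA): the bank
mixes px, px², ratios and grey levels, and the Kaiser eigenvalue-above-1
rule is only meaningful on the unit-variance scale. Zero-variance columns
(possible in small or noise-free samples, e.g. `ZeroPercent`) cannot be
standardized and are dropped with a recorded warning.

The decomposition is a dense symmetric eigensolve; determinism is pinned
by sorting eigenvalues non-increasing and flipping each eigenvector so
its largest-magnitude entry is positive. Retention defaults to a fixed
`k = 8` — the component count the reference study settled on for all
three size fractions — with the Kaiser rule available as an option.
Descriptor importance for a component is the absolute loading
(eigenvector entry × √eigenvalue), descending.

Model invariants asserted in tests: eigenvalue sum equals the matrix
trace (1e-10 relative), reconstruction residual below 1e-8, orthonormal
eigenvectors, diagonal score covariance with variances equal to the
eigenvalues (1e-6), and agreement with an independent SVD route.

## The perceptron and its training protocol

The classifier is an `n-h-1` perceptron: linear input units, one hidden
layer of logistic units with linear aggregation (linear PSP), one
logistic output. Training minimizes the sum-of-squares loss, consistent
with the RMS error `√(Σ(yᵢ−zᵢ)²/n)` used for reporting, in two phases:

1. **Back-propagation**: full-batch gradient descent for 10 cycles of
   1000 epochs, learning rate decreasing *linearly* from 0.2 to 0.1
   across all 10 000 epochs (the decay shape and its continuity across
   cycles are package choices; only the endpoints are given by the
   protocol), momentum 0.4, weights initialized uniformly on (−0.5, 0.5)
   under a per-model seed.
2. **Conjugate gradients**: 600 epochs of Polak–Ribière CG (PR+, with
   negative β clipped to a steepest-descent restart and a forced restart
   every `n_params` iterations) with backtracking Armijo line search, so
   the loss is non-increasing by construction.

`topology_search()` mirrors the reference protocol's model selection: 30
candidate hidden sizes (2–31), each trained on a stratified 50/25/25
train/validation/test split, winner chosen by validation percent-correct
with ties broken by validation RMS and then by fewer hidden units. The
test file never influences selection. Classification thresholds the
output at 0.5, boundary inclusive.

Gradient code is verified against central finite differences (relative
error < 1e-6) for hidden sizes 1, 8, 14 and 19, and the whole protocol is
exercised on XOR, where it reaches RMS < 0.05 in at least 90 of 100
seeded initializations.

## Validation problem sizes

The shipped validation uses: analytic shapes up to r = 75 px; 100 random
16×16 patches for the texture oracles; 100 random 50×10 datasets plus a
planted rank-3, 20-variable factor model (n = 200, factor sd 2 — chosen
to keep the noise bulk of the correlation spectrum below eigenvalue 1,
so the Kaiser criterion is well-posed) for the PCA identities; 100 XOR
seeds for the trainer; and a 200-grain, five-class synthetic study (50%
good, 20% mold, 10% each half/dehulled/dark-ends) for the end-to-end run,
in which segmentation must recover all 200 grains exactly and the
selected topology reaches at least 85% test-file quality with a
train–test gap of at most 10 points.

## Known limitations

* Synthetic kernels are far easier to classify than real bench images;
  the end-to-end quality numbers characterize the pipeline, not barley.
* Touching-grain separation, orientation normalization and photometric
  calibration are out of scope.
* Hue statistics are linear, which is acceptable for the yellow-tan
  palette of barley but wrong near the hue wrap-around.
* The Kaiser rule is exposed only for correlation-scale models; on raw
  covariances it is refused rather than silently misapplied.
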