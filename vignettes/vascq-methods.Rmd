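---
title: "Methods: self-supervised vascular segmentation and log-time growth models"
author: "vascq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-supervised vascular segmentation and log-time growth models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascq)
```

# Overview

`vascq` quantifies the growth of the embryonic zebrafish vasculature from
two-channel light-sheet time-lapses. The pipeline is: plan a mosaic of
overlapping acquisition volumes along the embryo; stitch the tiles of each
timepoint by phase correlation initialised from the stage positions; segment
the vasculature in 3D with a linear per-voxel classifier whose training
labels come from the circulating red-blood-cell (RBC) channel; propagate
manually drawn regions of interest backward through the projection time
series; measure isotropic voxel volumes per region; and fit growth models to
the resulting volume-versus-time curves, comparing log-time-rescaled models
against classical sigmoidal growth laws by residual sum of squares (RSS).

All computations are deterministic given the seeds recorded in the objects
they produce.

# Self-supervised segmentation

## Why a second channel

Vessels are hollow tubes: the endothelial marker labels only the wall, wall
intensity is heterogeneous (bright nuclei), and vessel diameters span an
order of magnitude. Plain thresholding or tube-filter approaches fail on
such data. RBCs, however, circulate strictly inside perfused vessels, so a
filtered and thresholded RBC channel is an inherent luminal proxy — free
training labels for a classifier of the endothelial channel, with no manual
annotation.

## Features

Six per-voxel features are computed from the endothelial channel
(`computeFeatureStack()`): the raw intensity, the three axis gradients
(central differences in voxel units, replicate edges), the Euclidean
gradient magnitude, and the inverse-gradient-weighted raw image
$f_6 = f_1 / (1 + f_5)$, which is large in bright flat regions (wall
centres, filled lumina) and suppressed at edges. Gradients use voxel rather
than micrometre units and the simplest symmetric stencil; the subsequent
per-feature z-scoring absorbs both the axis anisotropy and the overall
intensity scale, and makes the least-squares problem well conditioned. The
training-time means and standard deviations are stored in the model so a
fitted model can score other volumes consistently.

One practical caveat is intentional in the $f_6$ formula: the constant 1 in
the denominator is in intensity units, so the feature is informative on
camera-count scales (intensities well above 1) and degenerates towards $f_1$
on data normalised to $[0, 1]$. The pipeline therefore restores 16-bit count
scale when reading tiles.

## Training set

`sampleTrainingPoints()` samples candidate coordinates uniformly over the
whole volume, labels them positive if they fall inside the luminal proxy and
negative otherwise, and keeps the first $N$ of each class after a seeded
shuffle, without replacement ($N = 5000$ by default). The negative class is
then a faithful mixture of what non-luminal voxels look like: mostly dark
background with a minority of bright wall voxels.

This composition matters. We initially restricted candidates to the
neighbourhood of vessels ("hard negatives"). That variant is self-defeating
for a linear model: with the far background absent from training, the fitted
raw-intensity weight turns negative (the lumen is darker than the
wall-dominated negatives), and at scoring time the unseen dark background
outscores the lumen everywhere — the thresholded mask becomes the image
complement of the vasculature. With whole-volume sampling the weights are
brightness-driven with gradient corrections, the wall and lumen both score
above the background, and the intended mask emerges. The least-squares
compromise between "lumen = 1" and "wall = 0" leaves both well separated
from background, which is exactly what the downstream histogram threshold
needs.

## Solving, thresholding, cleaning

`fitFeatureWeights()` solves the linear system (six standardized features
plus a bias column against 0/1 labels) with the SVD pseudo-inverse, giving
the minimum-norm solution under rank deficiency; the fit residual is kept in
the model. `scoreVolume()` produces the score image;
`triangleThreshold()` applied to its 256-bin histogram (bins spanning the
full score range) picks the threshold, and a morphological opening with the
six-connected cross removes single-voxel fragments
(`morphologicalCleanup()`). The Triangle construction: draw the line from
the histogram peak to the far end of the longer tail and take the bin with
maximal distance between line and histogram; if the long tail is on the
left, mirror, solve, and mirror back. Bins are indexed from 0, following
image-histogram convention. The mask is `score > centre of the threshold
bin`; the opening uses the smallest structuring element that removes
isolated voxels while minimally thinning fine vessels.

# The synthetic phantom

`generateVesselPhantom()` builds the fixture every segmentation claim is
tested against. Vessels are tubes around random-walk centrelines with
bounded curvature (branching-free by design — sufficient to exercise
wall/lumen geometry). Ground truth: `truthWall` is the band within half a
wall thickness of the tube radius, `truthLumen` the interior, `truthVessel`
their union.

Image formation emulates, in order:

* **Wall signal**: a Gaussian shell whose FWHM equals the wall thickness
  (3 µm default), truncated at the truth wall edge, with a per-vessel
  amplitude drawn from `wallIntensityRange` (the intensity differences seen
  across real vessels).
* **Nuclei**: multiplicative bright blobs (σ = 1.5 µm) at Poisson positions
  along the wall — the dominant wall heterogeneity in real data.
* **Luminal fill**: a plasma/out-of-focus glow confined to the vessel
  interior at 35% of the wall amplitude, with a PSF-sharp boundary.
* **Scattered light**: 10% of a wide (σ = 6 µm) blur of the signal.
* **PSF**: isotropic Gaussian blur, σ = 0.8 µm.
* **Noise**: additive Gaussian, clipped at zero (Poisson noise is out of
  scope).

The RBC channel contains ellipsoidal speckles whose centres are kept at
least 3 µm inside the lumen boundary, so that after the proxy's Gaussian
smoothing the derived mask still lies ≥ 95% inside the true lumen.

The luminal fill deserves its design note. In real light-sheet data, vessel
interiors are never black: plasma autofluorescence, out-of-focus blood
cells and scattering fill large lumina with intermediate signal. This
component is also what makes the self-supervised scheme *learnable*: a
linear score can only separate lumen from background if some feature
differs between them, and in the endothelial channel that difference is the
luminal glow. Without it (a phantom with truly empty tubes), no weighting
of these six features can score the lumen above the background, and the
method — any linear method — fails by construction. The phantom is
therefore deliberately realistic in this respect, and the package's
segmentation accuracy on phantoms (Dice ≳ 0.9 at 128³, noise-free) should
be read as "the method works on data with luminal fill", not as a
statement about arbitrary hollow structures.

# Stitching

Registration is pairwise phase correlation (`phaseCorrelationOffset()`):
the strongest peaks of the normalized cross-power spectrum, disambiguated
for wrap-around, are screened within a search radius (default 20 px) of the
stage-derived initial offset and ranked by real-space normalized
cross-correlation of the implied overlap; a best correlation below 0.3
falls back to the nominal offset, flagged unreliable. Offsets are integer
voxels throughout — stage repeatability is sub-pixel and masks must stay
binary, so sub-pixel interpolation would buy nothing.

`globalizeOffsets()` fixes tile 1 at the origin and solves a score-weighted
linear least-squares problem for the remaining positions (per dimension);
unreliable pairs enter with their nominal displacement at low weight. A
disconnected adjacency graph is a hard error naming the components.
`fuseLinearBlending()` averages contributing tiles with
distance-to-border ramp weights (minimum border distance plus one), so
seams fade linearly and single-tile regions are copied unchanged. For 3D
stacks, registration runs on z maximum-intensity projections and the
refined in-plane offsets are applied to the stacks with nominal z offsets —
computed per timepoint; a saved offset set can be reapplied when drift-free
acquisition warrants it.

# ROI propagation

Annotation is drawn once, at the last timepoint, and propagated backward
(`propagateRoi()`). Per boundary point: a 70 × 70 px template around the
point at time $t$ is matched by zero-normalized cross-correlation
(illumination-robust, `matchTemplate()`) inside a concentric 140 × 140 px
window at $t-1$; ties break towards the smallest displacement, then
row-major. Raw shifts are regularized componentwise by a median over a
centred circular window of seven boundary points (the point itself plus
three neighbours each side — the most natural reading; boundaries shorter
than seven use the global median). Points landing on identical or
8-adjacent pixels are merged by a forward scan (no wrap-around check, and
no re-insertion when the boundary stretches — backward point counts are
non-increasing); fewer than three surviving points is a collapse error
naming the timepoint. Window sizes are defaults, exposed for differently
scaled projections.

# Quantification

`measureVolume()` resamples a mask to isotropic spacing — nearest
neighbour, at the finest existing spacing, so binarity is preserved and no
information is discarded — and multiplies the voxel count by the isotropic
voxel volume; both the count and the physical volume are reported.
`measureRegionVolumes()` resamples mask and label image with the same index
map, so per-region volumes (plus the unlabelled remainder, "other")
partition the whole-mask volume exactly. Two viewing angles of the same
fish are averaged pointwise (`combineAngles()`), and per-fish time shifts —
determined manually from the anastomosis of the left and right primordial
hindbrain channels, and supplied as inputs — are applied with
`alignTime()`.

# Growth models

Six models share the asymptote convention $V(t) \to A$ (volume present at
the start of observation) and $V(t) \to A + V_L$ (full observed growth):

* scaled cumulative **log-logistic**: $V = A + V_L/(1 + (t/\alpha)^{-\beta})$
* scaled cumulative **log-normal**: $V = A + V_L\,\Phi((\ln t - \mu)/\sigma)$
* **Gompertz**: $A + V_L \exp(-\exp(-k(t - t_i)))$
* **logistic**: $A + V_L/(1 + \exp(-k(t - t_i)))$
* **Weibull**: $A + V_L(1 - \exp(-(t/\lambda)^k))$
* **Richards**: $A + V_L(1 + \nu \exp(-k(t - t_i)))^{-1/\nu}$

The classical four are not printed in the source material; the forms above
are the standard four-parameter versions with the offset added so every
model has the same $A$/$V_L$ semantics and RSS values are comparable.
Analytic rates (`modelRate()`) use overflow-safe forms at extreme
arguments. Peak growth times (`peakGrowthTime()`) have closed forms —
log-logistic $t^* = \alpha((\beta-1)/(\beta+1))^{1/\beta}$ for $\beta > 1$,
log-normal $t^* = e^{\mu - \sigma^2}$, Weibull
$\lambda((k-1)/k)^{1/k}$ for $k > 1$, and $t_i$ for the three
inflection-parameterised models — each cross-checked against a numeric
argmax in the tests; parameter regimes without an interior maximum return a
boundary flag.

## Fitting

`fitGrowthModel()` minimises the RSS with the Levenberg–Marquardt
algorithm (`minpack.lm`), one solver for every model and dataset rather
than a two-family scheme. Positive parameters are fitted on the log scale
so the solver stays unconstrained. Initialisation is data-driven: $A_0$ and
$V_{L0}$ from the series range, time-scale parameters from the interpolated
half-rise time, shape parameters from the interquartile rise span; ten
multiplicative restarts jitter the transformed start under a fixed seed.
Non-convergence is reported by flag, never by exception, and a fit that
collapses to vanishing amplitude (constant data) sets a boundary flag.
`compareModels()` fits a model list and ranks by RSS, returning residual
vectors for inspection.

## What the simulations show

The canonical example parameters (`exampleGrowthParams()`) place the peak
growth rate near 26 hours post fertilisation — the observed timing for the
whole vasculature — with volumes on the 10⁷ µm³ scale, and a log-normal
σ of 0.6, i.e. the strongly right-skewed fast-rise/slow-decay rate shape
that motivates log-time models in the first place. On data simulated from
these log-time models at low noise, both log-time models outperform all
four classical models by RSS; this mirrors, at simulation level, the
empirical finding that growth-law fits to real vascular volumes require
logarithmic time rescaling. It is a property of the simulated curves and
their window (17–89 hpf), not a re-derivation of the real-data result: for
mildly skewed curves (log-normal σ ≲ 0.45) Gompertz and Richards
approximate the window well enough to win, so the distinguishability of
model families genuinely depends on the skew of the underlying growth.

# Problem sizes and numerical choices

Tests and the acceptance script run the segmentation benchmark on a
128³ noise-free phantom (two-to-three vessels, the package defaults),
stitching on three-tile sets with ±5 px jitter over ten seeds, parameter
recovery on n = 100 series at 2% noise over 20 seeds, and model comparison
at 0.5% noise — sizes chosen so the whole suite completes in a few minutes
while leaving the conclusions unchanged at larger sizes. Oracle agreement
(SVD weights versus a dense pseudo-inverse) is asserted at 10⁴ × 7 to
1 × 10⁻⁸ relative. Degenerate inputs — flat RBC volumes, single-class
training sets, constant score images, zero-variance templates, collapsed
boundaries, disconnected tile graphs — return flagged results or named
errors rather than propagating nonsense.

# Known limitations

* The phantom has no branching, no photobleaching, no drift, no Poisson
  noise, and no multi-view fusion artifacts; passing tests say nothing
  about those regimes.
* The segmentation model is linear; it relies on luminal fill and cannot
  segment truly empty tubes (see above). Per-stack refitting is the
  default; model reuse across timepoints is supported but unvalidated.
* Stitching assumes translation-only misalignment, as justified by precise
  stages; rotation and scale are out of scope, as is cross-channel fine
  registration.
* Temporal alignment shifts are inputs; the anatomical landmark is not
  detected automatically.
* RSS is the only model-selection criterion (with residual inspection);
  information criteria are deliberately not implemented.
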