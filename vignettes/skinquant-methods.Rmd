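---
title: "Volumetric morphometry of layered skin equivalents: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric morphometry of layered skin equivalents: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinquant)
```

`skinquant` quantifies the three compartments of an engineered human skin
culture from multi-channel confocal stacks: the epidermal layer (thickness
and suprabasal marker expression), the hypodermal adipose compartment
(lipid volume fraction, layer thickness, integrated stain intensity), and
the self-assembled dermal vasculature (vessel diameters, volume fraction,
and a diffusion-length statistic). A UVA dosimetry and group-statistics
layer turns per-sample metrics into the comparisons a photoaging experiment
needs. Because no public volumes accompany such cultures, the package ships
a seeded phantom generator whose exact geometric ground truth drives every
test.

## The image model and its assumptions

All volumes are carried as `voxel_grid` objects: `(z, y, x)`-ordered
non-negative intensity arrays with physical voxel dimensions in
micrometres. The default geometry is strongly anisotropic — 0.7 µm
laterally and 3 µm axially — and the package treats that asymmetry as a
first-class property: plane-wise filters never mix z-planes, Gaussian
scales are specified in micrometres and converted per axis, and every
distance or thickness is computed in physical units.

Three assumptions underlie the pipelines:

* structures of interest are *bright on dark* (fluorescence), so
  segmentation everywhere is hysteresis thresholding at fractions of the
  volume maximum — invariant to global intensity scaling;
* background autofluorescence varies smoothly within a plane, so a
  rolling-ball opening estimates and removes it;
* layers (epidermis, adipose) are z-contiguous per column after
  morphological cleanup, so a column's thickness is the span between its
  outermost occupied planes.

## Pre-processing and segmentation

Each channel passes through median filtering (window `(2r+1)^2`, reflected
edges), linear rescaling to `[0, 1]`, and rolling-ball background
subtraction; the epidermal pipeline then fuses nuclei, cytokeratin-10 and
involucrin channels by voxelwise maximum (the markers label different
strata; their union localizes the layer) before hysteresis thresholding and
plane-wise disk closing/opening.

The rolling ball deserves a caveat: a grayscale opening with a hemisphere
structuring element returns exactly the input on a *constant* plane, so any
structure that is both broad and featureless is removed wholesale.
Epidermal planes in real stacks are never featureless — cell borders and
nuclei impose ~30–50 % intensity texture at a 2–5 µm correlation length —
and the surviving texture peaks are what the subsequent thresholding and
closing reconstruct into the layer. This is why the default hysteresis
thresholds are comparatively low (0.10/0.40 of the maximum) and the default
cleanup disk comparatively large (6 px ≈ 4.2 µm): with background
subtraction in the chain, slab voxels present as sparse peaks, and the
closing element must bridge inter-peak gaps. With the defaults, segmenting
a textured 90 µm slab under 10 % Gaussian noise overlaps the true slab at
Dice above 0.9 and recovers the median thickness to within one z-step
(both asserted by the test suite); with markedly higher thresholds the
peaks fall below the low threshold and the layer fragments. For
background-free volumes (synthetic or pre-corrected), pass
`filter_params(rolling_ball_radius_px = NULL)` to skip the stage; then
segmentation of a noiseless slab is exact.

For radii above 16 px the rolling ball runs on a block-minimum downscaled
plane and the background is bilinearly upsampled — the standard
large-radius strategy; the approximation error is well below the texture
amplitudes the stage is meant to preserve.

## Thickness

`thickness_map` reduces a binary layer to a per-column measurement:
`(z_top − z_bottom + 1) × dz` where the `+1` voxel-count convention makes a
one-plane layer read `dz` rather than zero. Columns crossing internal gaps
use outermost extents — the morphological closing that precedes the map is
responsible for deciding which gaps are real. Summaries pool valid columns
across sub-volumes by default; per-tile means are also reported so the
average-of-tile-averages ordering is available (both orderings agree to
well under a z-step on homogeneous layers, and pooling weights every column
equally when tiles differ in valid area).

Adipose thickness reuses the same machinery after bridging the droplet
mask with a larger closing disk (default 8 px): lipid droplets are discrete
spheres, and the closing turns a droplet *layer* into a measurable slab.
The bridge radius trades gap tolerance against halo: it should exceed half
the typical inter-droplet spacing but stay below the layer thickness.

## Vascular analysis

Vessel enhancement is the classic multiscale Hessian tubularity measure.
At each physical scale `s` the volume is smoothed with per-axis sigma
`s / voxel_dim`, the Hessian is computed by central differences over
physical coordinates and normalized by `s²`, and its eigenvalues
`|λ1| ≤ |λ2| ≤ |λ3|` enter the response
`(1 − exp(−R_A²/2α²)) · exp(−R_B²/2β²) · (1 − exp(−S²/2c²))` for
`λ2, λ3 < 0`, with `R_A = |λ2|/|λ3|` (plate vs line), `R_B = |λ1|/√|λ2λ3|`
(blob rejection) and `S` the Frobenius norm (noise floor); `α = β = 0.5`
and `c` set to half the maximal Hessian norm per scale unless overridden.
Working with per-axis sigmas rather than resampling the volume to an
isotropic grid keeps the filter free of interpolation artifacts and
memory copies; the cost is that scales below the z-step are effectively
unsmoothed along z, which is the physically honest behaviour.

Segmentation of the response reuses hysteresis (defaults 0.3/0.6 of the
response maximum, chosen where recovered volume fraction tracks rasterized
truth within a few percent on anisotropic tube grids) plus removal of
components under 20 voxels.

Skeletonization is contract-driven: any algorithm producing a 1-voxel-wide
centreline inside the mask that preserves per-component connectivity and
tracks a cylinder's axis to within a voxel is acceptable. The
implementation is homotopic thinning guided by the Euclidean distance
transform: voxels are visited level-by-level in increasing
distance-to-background, and removed only when they are (26,6) simple
points — removal changes neither foreground 26-topology nor background
6-topology — and not curve endpoints. Two details matter in practice.
First, deletions within one sweep are restricted to an independent set (no
two removed voxels 26-adjacent) with sweeps cycling over the six face
directions; without this, a deletion front can run along an even-cored
tube and consume it longitudinally. Second, where a flat structure end
collapses, the surviving endpoint tail can slide off the distance ridge;
tails are therefore trimmed back to their maximal-EDT voxel and regrown
along the ridge with direction continuity. Radius-scale spurs terminating
at junctions are pruned.

Diameters sample the anisotropic Euclidean distance transform of the mask
at skeleton points (`diameter = 2 × EDT`). The EDT is exact — the separable
lower-envelope algorithm on squared distances with per-axis physical
spacing — and uses the centre-to-centre convention: an isolated single
voxel reads one voxel-unit radius. Digitization biases diameters of thin
tubes upward by up to half a lateral voxel; on tube phantoms with radii
3–8 µm the recovered medians are strictly ordered and stay inside the
25 % digitization tolerance the tests assert.

The diffusion length `R_k` is the 0.90 quantile (linear interpolation,
`quantile type 7`) of the distance from every *tissue* (non-vessel) voxel
to the nearest vessel voxel — the radius around the network that reaches
90 % of the tissue volume. Vessel voxels themselves are excluded from the
quantile: the statistic describes tissue-to-network distance, and
including the zero distances would only dilute the quantile at high volume
fractions. `diffusion_length` and the exhaustive `brute_force_rk` oracle
compute squared distances with the same accumulation order, so they agree
to machine precision, which the test suite asserts on random anisotropic
masks up to 32³.

Per-sample aggregation follows the fields-of-view design: metrics are
means over sub-volumes within a sample; group summaries then use medians
across samples.

## Dosimetry and statistics

Radiant exposure is plain arithmetic, kept exact:
`daily [J/cm²] = irradiance [mW/cm²] × 3600 × hours / 1000`, total = daily
× days. The measured irradiance tolerance (±0.15 mW/cm²) widens into a
reported min/max dose interval but is not propagated into statistics — the
mean irradiance defines the exposure. For the study schedule (0.45 mW/cm²,
2 h/day, 7 d) this gives 3.24 J/cm² per day and 22.68 J/cm² total.

Group comparisons normalize to the control-group mean (controls average
to 1; treatment values read as fold change), then use a two-tailed
unpaired t-test for two groups or one-way ANOVA with Tukey's HSD beyond
two. The t-test defaults to pooled variance — the conventional choice when
group variances are comparable, as they are for replicate cultures — with
Welch available via `var_equal = FALSE`. Significance is flagged at 0.05
(`*`) and 0.01 (`**`).

## The phantom generator

The generator produces, deterministically from `(spec, seed)`:

* an **epidermal slab**: per-column thickness is a smoothed Gaussian field
  (defaults 90 ± 5 µm, 10 µm lateral correlation) rasterized from a fixed
  top plane; channels share a multiplicative cellular texture (amplitude
  0.5, 3 µm correlation) because featureless slabs are not a meaningful
  test of a pipeline containing background subtraction; the truth records
  exact per-column extents;
* **vessel tubes**: solid capsules around polyline axes rasterized in
  physical µm space (a voxel is foreground when its centre lies within the
  radius), so anisotropy errors surface in tests; truth stores the
  rasterized volume fraction, axes and radii, plus the analytic cylinder
  volume;
* **lipid droplets**: non-overlapping spheres rejection-sampled into a
  basal z-layer; droplet intensity is a free parameter at fixed geometry,
  so photoaging-style lipid loss can be emulated as pure intensity
  reduction — the mechanism behind the package's key dissociation check
  (halving intensity halves the masked integrated intensity within 2 %
  while volume fraction and thickness move by ~1–2 %);
* **noise**: a linear background ramp of random in-plane direction, sparse
  Gaussian autofluorescent blobs, and pixelwise Gaussian noise, clipped at
  zero. Clipping an empty background leaves a sample whose SD is
  `sqrt(1/2 − 1/2π) ≈ 0.584` of the nominal sigma; moment tests correct by
  that factor.

What the phantoms deliberately do not model: the confocal point-spread
function and depth-dependent attenuation, spectral bleed-through,
stitching seams, and any biological mechanism of photoaging beyond
geometry/intensity knobs. Passing tests therefore demonstrate that the
measurement chain is correct on data satisfying its stated assumptions,
not that those assumptions hold for any particular microscope.

## Numerical conventions and degenerate inputs

* Reflect (symmetric) padding for all plane-wise filters, avoiding dark
  rims that would bias thickness at tile borders.
* Hysteresis connects in 3D with 26-connectivity — permissive linking
  across the coarse z-step.
* A constant volume rescales to all-zero with a warning; a constant lipid
  channel segments to an empty mask with a warning; an empty mask yields
  an all-invalid thickness map, and summaries over all-invalid maps error.
* `diffusion_length` on an all-vessel mask is 0; on an empty vessel mask
  it errors (the distance is undefined).
* Quantiles are `type 7` (linear interpolation) throughout.

## Problem sizes

The test suite and the acceptance script run on sub-volumes chosen to keep
every geometric feature several voxels wide while completing in minutes:
epidermal phantoms of 45 × 96 × 96 voxels (≈ 9,200 columns at the study
voxel size), adipose phantoms of 50 × 110 × 110 with 20 droplets of
6–12 µm, diameter-recovery tubes in 128³ isotropic volumes, oracle
comparisons on ≤ 32³ masks, and a clustered-capillary study phantom of
40 × 400 × 200 anisotropic voxels whose volume fraction sits in the
few-percent regime of self-assembled dermal networks. The clustered
layout matters: uniformly spaced tubes at a few percent volume fraction
would put 90 % of tissue within ~20 µm of a vessel, whereas real
self-assembled networks are heterogeneous, leaving poorly vascularized
pockets that dominate the upper distance quantiles.

## Known limitations

* Sub-voxel surfaces are not estimated: thickness is quantized to the
  z-step, and diameters inherit up to half a lateral voxel of
  digitization bias (documented and covered by tolerances in tests).
* The thinning skeleton is a curve skeleton; plate-like segmentation
  artifacts are collapsed to curves, which is correct for vessels but
  would be wrong for sheets.
* Marker intensity is measured on unsegmented maximum projections without
  background correction, matching the whole-field readout it mirrors; it
  is therefore sensitive to autofluorescent background if that differs
  between groups.
* The vesselness filter under-segments tubes thinner than about one
  z-step (the response exists but the mask loses z-coverage), biasing
  volume fractions low in the capillary regime; diameters are more robust
  because they are read at the centreline.
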