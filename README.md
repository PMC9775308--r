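# skinquant

Volumetric morphometry for engineered human skin equivalents imaged by
confocal microscopy.

Tissue-engineered skin cultures with an epidermis, a vascularized dermis
and a hypodermal fat compartment are increasingly used to study skin aging
— in particular UVA photoaging, which acts mainly below the epidermis.
Evaluating such cultures means measuring, in three dimensions and in
physical units, how thick the epidermal layer is, how much lipid the
hypodermis holds, and how dense and fine the self-assembled vascular
network is. `skinquant` implements that measurement chain for
anisotropic-voxel confocal stacks (default 0.7 × 0.7 × 3 µm), together
with the UVA dosimetry and the group statistics such an experiment needs,
and a seeded phantom generator with exact geometric ground truth that
backs every claim with a test.

## What it computes

**Epidermis** — channels (nuclei, cytokeratin 10, involucrin) are median
filtered per plane, rescaled, rolling-ball background corrected, fused by
voxelwise maximum, hysteresis thresholded and cleaned by disk
closing/opening. Per image column the layer thickness is
`(z_top − z_bottom + 1) · dz` µm; suprabasal marker expression is the mean
of pooled maximum projections.

**Adipose** — BODIPY droplet segmentation, then three readouts: lipid
volume fraction; layer thickness after closing the droplet mask into a
slab; and the integrated intensity `Σ I(x)` of the raw channel over the
mask, averaged across sub-volumes. Because the mask is built from
intensity *fractions* while the integral is *linear* in intensity, lipid
loss at constant droplet geometry moves the integral proportionally while
leaving the morphological measures nearly unchanged — the dissociation
that distinguishes lipid depletion from cell loss.

**Vasculature** — multiscale Hessian (Frangi) vesselness

    V = (1 − e^{−R_A²/2α²}) · e^{−R_B²/2β²} · (1 − e^{−S²/2c²}),  λ₂, λ₃ < 0

with anisotropy-aware physical scales; hysteresis segmentation;
homotopic 3D thinning to a centreline; per-point diameters `2 × EDT`
from an exact anisotropic Euclidean distance transform; vascular volume
fraction; and the diffusion length `R_k` — the 0.90 quantile of the
distance from every tissue voxel to the nearest vessel, i.e. the radius
around the network that covers 90 % of the tissue.

**Dosimetry & statistics** — radiant exposure
`J/cm² = mW/cm² × s / 1000`, control-mean normalization, pooled-variance
t-tests and ANOVA + Tukey HSD with `*`/`**` flags at 0.05/0.01.

**Phantoms** — slabs with per-column ground-truth extents, capsule-
rasterized tube networks, non-overlapping droplet layers, structured
noise; all pure functions of `(spec, seed)`, plus an exhaustive
`brute_force_rk` distance oracle.

## Worked example

```r
library(skinquant)

# UVA dose for the photoaging schedule
radiant_exposure(0.45, hours_per_day = 2, days = 7, tolerance_mw_cm2 = 0.15)
#> <dose_result> 3.24 J/cm2 per day, 22.68 J/cm2 total (interval 15.12-30.24)

# a synthetic stack at study conditions: 90 um epidermis, 10% noise
spec <- phantom_spec(shape_vox = c(45, 96, 96), voxel_size = c(3, 0.7, 0.7),
                     epidermis = list(mean_thickness_um = 90, sd_um = 5,
                                      surface_roughness_um = 10),
                     noise = list(gaussian_sd = 0.1), seed = 7)
ph <- make_epidermis_phantom(spec)
chans <- lapply(list(ph$nuclei, ph$k10, ph$involucrin),
                apply_noise, noise = spec$noise, seed = spec$seed)
mask <- segment_epidermis(chans[[1]], chans[[2]], chans[[3]])
summarize_thickness(thickness_map(mask))
#> <epidermis_result> median 90.00 um, mean 90.23 um over 1 sub-volume(s) (valid 100.0%)

# vessels: tube phantom -> vesselness -> mask -> skeleton -> metrics
vspec <- phantom_spec(shape_vox = c(40, 96, 96), voxel_size = c(3, 0.7, 0.7),
                      vessels = parallel_tubes(c(40, 96, 96), c(3, 0.7, 0.7),
                                               spacing_um = 40, radius_um = 5))
vp <- make_vessel_phantom(vspec, blur_sigma_um = 1)
v <- vesselness(vp$col4, scales_um = c(3, 5, 8))
net <- vessel_network(segment_vessels(v))
vascular_metrics(net)
#> <vascular_result> median diameter 7.00 um, VF 0.0620, R_k 17.4 um (coverage 90%, n = 1)
```

The dose is the exact schedule arithmetic. The recovered median thickness
matches the generator's 90 µm field; the mean differs because thickness is
quantized to the 3 µm z-step. For the 10 µm tubes the pipeline reads a
7.0 µm median diameter (thin tubes lose z-coverage at a 3 µm axial step; a
documented bias) and a short diffusion length, as expected for a dense
regular grid — real self-assembled networks are clustered and reach R_k
values several times larger at the same volume fraction.

Real stacks enter through `read_stack("stack.tif", voxel_size = c(3, 0.7, 0.7))`
(one grayscale multi-page TIFF per channel) and are tiled into analysis
sub-volumes with `extract_subvolumes()`.

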