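---
title: "Quantifying retinal microvasculature on OCTA en face angiograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal microvasculature on OCTA en face angiograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaquant)
```

## The measurement problem

En face OCTA angiograms map perfused retinal vessels over a 3 × 3 mm
macular field sampled on a 245 × 245 grid (about 12.2 µm per pixel), one
image per capillary plexus (superficial, SCP; deep, DCP). The quantities of
clinical interest are small summary numbers per eye: vessel density (VD,
skeleton length per area), perfusion density of large vessels (PD, an
areal percentage), box-counting fractal dimension (FD), and the area of
the foveal avascular zone (FAZ). All region-based metrics are measured
inside a fovea-centered annulus of inner diameter 1 mm and outer diameter
2.5 mm, with the manually outlined FAZ masked out so that eyes with a
physiologically large avascular zone are not penalized by definitionally
vessel-free area.

This vignette records how each step is defined here, the choices that were
genuinely open, and what the synthetic validation does and does not show.

## Image processing chain

**Coordinate frame.** The origin sits at the centre of the top-left pixel;
x runs along columns and y along rows, in mm. A pixel is an
`mm_per_pixel` square, so any mask area is (pixel count) × pitch².
Polygons (FAZ boundaries) live in the same frame, so raster and vector
geometry compose without offsets.

**Vessel enhancement.** `hessian_vesselness()` implements an
eigenvalue-based tubularity filter: at each Gaussian scale σ the Hessian
eigenvalues |λ₁| ≤ |λ₂| are combined into
exp(−R_b²/2β²)·(1 − exp(−S²/2c²)) for bright structures (λ₂ < 0), with
R_b = λ₁/λ₂ suppressing blobs, S the Frobenius norm rewarding contrast,
γ = 2 scale normalization, β = 0.5, and c set per scale to half the
maximum Hessian norm. The default scales {2, 3, 4} px put the response
peak at vessels of roughly 30 µm diameter and above at the 12.2 µm pitch,
which is what separates photograph-visible vessels from the capillary
mesh.

**Binarization.** A pixel is vessel if it exceeds its 11 × 11 local mean
by an offset, *or* exceeds the global Otsu threshold. The local branch
adapts to shading; the Otsu branch recovers the interior of structures
wider than the window, which a pure local-mean rule hollows out. The
offset is estimated from the data as three times a robust noise SD
(Immerkær's Laplacian-kernel estimator, median-based), floored at 0.04:
a fixed zero offset would mark half of all background pixels as vessel
under any noise at all. Connected components below 5 px are removed as
speckle. The whole decision depends only on intensity order and contrast,
so rescaling raw intensities (or re-encoding 8-bit vs 16-bit) does not
change the mask.

**Large-vessel detection** (SCP only; the deep plexus has no
photograph-visible vessels and PD is undefined there, so DCP input is an
error). A core pixel must both respond to vesselness at the large scales
(threshold 0.25 of the per-image maximum) and have a distance-transform
half-width of at least 1.5 px (width ≥ 3 px ≈ 37 µm); cores are grown
back to the full vessel width within the binary mask. The two conditions
are deliberately redundant: the width floor pins the definition to
physical size, the vesselness term rejects blob-like capillary junctions
that can pass a pure width test.

**Skeletonization and length.** Zhang–Suen thinning yields a one-pixel,
8-connected skeleton; two standard post-passes matter for length
fidelity. First, thinning leaves *staircase corners* (pixels whose only
two neighbours are perpendicular orthogonal pixels); counted with the
(1, √2) chain rule these inflate oblique lengths by several percent, so
such corners are removed when connectivity is preserved. Second, thinning
retracts tube ends by about half a width; endpoints are therefore marched
along their local direction while still inside the source mask. Skeleton
length is then the sum over adjacent skeleton-pixel pairs — 1 per
orthogonal step, √2 per diagonal, each adjacency once, with a diagonal
dropped whenever it closes a right-angle triangle that an orthogonal
chain already traverses (otherwise lengths overcount by up to 41%).
On validation fixtures this chain (bar fixtures, two-resolution
renderings of one physical scene) agrees with analytic lengths to within
1–3%.

**Region metrics.** Annulus membership uses pixel centres with the
half-open interval [inner, outer), so adjacent rings never double-count a
pixel. The FAZ centroid (area centroid by the shoelace decomposition)
centres the annulus; each plexus uses *its own* FAZ centroid and area,
since the deep plexus' avascular zone is substantially larger. VD divides
the in-region skeleton length by the region area; PD is the in-region
large-vessel pixel fraction × 100. FD counts occupied boxes on a
power-of-two ladder from 2 px to a quarter of the shorter image side,
anchored at the region's bounding-box corner, and takes the OLS slope of
log N(s) vs log(1/s). On analytic sets the estimator lands within 0.05 of
the true dimension (filled square 1.96, line 0.98, level-5 Sierpinski
carpet 1.853 vs log 8/log 3 = 1.893 — the power-of-two ladder on a
3-adic fractal accounts for the residual bias).

**VD substrate.** The definition of VD does not exclude large vessels, so
the default skeleton is the full binarized plexus; `capillary_only_vd`
subtracts the large-vessel mask first for sensitivity analyses. Reported
VD is in mm/mm² (equivalently mm⁻¹); published tables sometimes label
this "%", but the magnitudes (≈ 15–21) are length-per-area values and no
rescaling is applied here.

## Synthetic scenes and what they validate

`generate_vessel_network()` emulates the *measurement substrate*, not
retinal biology: large vessels are smooth random-walk polylines of
constant width (30–80 µm), capillaries a jittered square mesh of short
1–2 px segments thinned to a target length density, the FAZ a jittered
ellipse rescaled to its target area (0.31 mm² SCP, 1.11 mm² DCP) and kept
vessel-free with a margin; vessels render bright on a dark background,
are blurred at half-pixel sigma and covered with additive Gaussian noise
(SD 0.05 by default, mapping to signal strength 8 on the 0–10 scale).

Two generator choices deserve justification:

- **Capillary density 12 mm/mm².** Anatomical intercapillary spacing
  (50–100 µm) is at or below the 12.2 µm/px raster's ability to render
  separable 1–2 px tubes; a mesh at clinical VD magnitudes (15–21 mm⁻¹)
  would fuse into plaques and the ground truth would stop meaning
  anything. The default keeps the mesh resolvable; consequently synthetic
  VD and FD values sit below clinical magnitudes, which is irrelevant to
  what the scenes are for — known truth.
- **No capillary/large-vessel overlap.** Mesh edges entering the dilated
  large-vessel footprint are rejected. Anatomically capillaries
  anastomose onto larger vessels rather than running through their lumen;
  from a truth-accounting view, centerline length hidden under a wide
  vessel is unmeasurable by any skeleton and would bias every recovery
  comparison by construction.

The ground truth carries the analytic centerline length; for in-region
comparisons, `scene_region_length()` integrates the centerlines over the
region's pixels, independent of any rasterization (a rasterized truth
chain would itself carry +5% chain-code bias and junction-union
artifacts). Against this oracle the full pipeline (render → binarize →
thin → count) recovers VD within ±2% over 20 seeded scenes; residual
error is a near-cancellation of chain-code overestimation on oblique
straight runs and shortcutting at junction blobs.

What the scenes do *not* emulate: OCTA speckle statistics and flow-signal
dropout, projection artifacts, motion artifacts, and curvilinear
capillary morphology. Passing the recovery tests shows that the geometry
and counting machinery is correct, not that segmentation performance on
device-exported angiograms equals the synthetic Dice (≥ 0.95 here).

## Synthetic cohorts and the statistics stage

`generate_cohort()` draws per-group covariates (age, sex, race, diabetes,
blood pressure, signal strength) from configured distributions matching a
90-participant memory-clinic case-control cohort (24 AD / 37 MCI / 29
controls), and builds each OCTA metric as control baseline + group offset
+ covariate terms + Gaussian residual. Covariates enter *centered at the
pooled expected profile*, so the configured baseline is also the expected
covariate-adjusted control mean and the planted offsets are exactly what
the regression stage should recover. The default offsets plant the
published-magnitude effects (e.g. −0.88 on SCP VD for AD); default
covariate slopes are modest and chosen only to make adjustment
non-trivial (density falls with age and diabetes, tracks scan quality).

Open choices resolved here:

- **Adjusted means.** "Adjusted mean ± SD" is not a uniquely defined
  estimator; this package predicts at the pooled sample-mean covariate
  vector with categorical covariates at their sample proportions
  (proportionally weighted estimated marginal means, cross-checked
  against emmeans). This makes β ≡ adjusted-mean difference an exact
  algebraic identity, which the tests assert on every fit. Both the raw
  group SD and the model SE are reported, labelled, since the published
  "±" could be either.
- **Post hoc power.** The normal-approximation unequal-variance formula
  Φ(|Δ|/SE − z₁₋α/₂); on the two published input sets it returns 80.6%
  and > 99.99% (printed 80.5% and 100%). At Δ = 0 it degenerates to α/2
  exactly, which the tests use as the null anchor.
- **Exclusion precedence.** Reasons are tallied fatigue → quality → eye
  disease, first match counted, so the tally always sums to enrolled −
  included regardless of flag overlap.
- **Paired AUC comparison.** DeLong structural components with a
  two-sided normal reference; a self-comparison (zero-variance
  difference) reports p = 1 by convention. Type-I error is verified at
  0.05 ± 0.02 over 1000 null replicates at n = 200.
- **ROC conventions.** AUC by the rank formulation with ties counted ½,
  reported as-is (below-chance markers are flagged, not flipped);
  sensitivity at fixed specificity linearly interpolates the ROC
  polyline, so an all-ties marker returns the chance diagonal. The 41.5%
  specificity operating point is exposed as a parameter with that
  default.
- **Bonferroni family.** α/k with k = 2, reflecting a primary (VD, FD)
  and secondary (PD, FAZ) outcome family.

## Problem sizes in the validation suite

The suite runs at sizes chosen to keep Monte-Carlo error well inside the
asserted bands: 20 seeded scenes for VD recovery, 1000 null replicates
(n = 200) for the DeLong test size, 200 cohort replicates for CI
coverage, 100 replicates at n = 500/group for planted-effect recovery,
and 10⁴ draws for eye-selection uniformity. A full scene through the
image chain takes well under a second, so the whole suite completes in
about a minute.

## Known limitations

- Skeleton-based VD carries the (1, √2) chain-length estimator's
  orientation-dependent bias (up to +8% on isolated oblique lines); on
  mesh-like vasculature it largely cancels against junction shortcutting,
  but single-vessel length readouts inherit it.
- The box ladder and box anchoring are one of several defensible
  conventions; published FD values from other toolboxes can differ by a
  few hundredths on identical masks.
- No axial-length magnification correction: the mm scale is taken from
  the scan metadata as-is.
- Eligibility filtering models eye-level quality only through signal
  strength; motion and segmentation artifacts, which a human grader also
  screens, are outside the synthetic model.
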