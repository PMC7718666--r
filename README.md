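# octaquant

Quantification of the retinal microvasculature from en face OCTA
angiograms, with covariate-adjusted cohort statistics.

Optical coherence tomography angiography (OCTA) produces en face maps of
perfused retinal vessels for the superficial (SCP) and deep (DCP) capillary
plexuses. Studies of neurodegenerative and vascular disease summarize these
maps with a small set of metrics measured inside a fovea-centered annulus
(inner diameter 1 mm, outer diameter 2.5 mm) after masking out the manually
delineated foveal avascular zone (FAZ):

- **Vessel density (VD)** — total perfused-vessel centerline length per
  unit area, in mm/mm². The binarized plexus is skeletonized to one-pixel
  width and the length is the sum over adjacent skeleton-pixel pairs of
  step lengths (1 for orthogonal, √2 for diagonal neighbours, each
  adjacency counted once, diagonals closing a right-angle triangle
  dropped), scaled by the pixel pitch and divided by the region area.
- **Perfusion density of large vessels (PD)** — the percentage of the
  region occupied by large (non-capillary) vessels, detected with a
  Frangi-type Hessian vesselness filter combined with a distance-transform
  width floor (SCP only).
- **Fractal dimension (FD, D_box)** — the box-counting dimension of the
  binarized vasculature inside the region: the slope of log N(s) against
  log (1/s) over a power-of-two ladder of box sizes.
- **FAZ area** — the shoelace area of the FAZ boundary polygon, per plexus.

The statistics stage reproduces the standard analysis around these
metrics: eligibility filtering (signal strength ≥ 7, fatigue and eye
disease exclusions), one random analysis eye per participant, baseline
ANOVA / chi-square comparisons, multivariable linear regression adjusted
for age, gender, race, diabetes, blood pressure and scan signal strength
(with proportionally weighted estimated marginal means, so that the group
coefficient β equals the adjusted-mean difference exactly), Bonferroni
control across the outcome family (α = 0.05/2 = 0.025), ROC/AUC with
DeLong paired comparisons and sensitivity at a fixed specificity, and
normal-approximation post hoc power
Φ(|Δ|/√(s₁²/n₁ + s₂²/n₂) − z₁₋α/₂).

Because no public angiogram or patient data accompany the design, the
package ships a first-class synthetic generator: angiogram scenes with
branching large vessels, a jittered capillary mesh, a vessel-free FAZ,
blur and speckle noise — with exhaustive ground truth (centerlines,
masks, analytic skeleton length, FAZ polygon) — and synthetic cohorts
with configurable covariate distributions and planted group effects.
Every stage is validated end-to-end against this truth.

## Worked example

```r
library(octaquant)

# one synthetic eye: SCP with large vessels, DCP mesh-only
scene <- generate_vessel_network(angio_scene_params(plexus = "SCP", seed = 42))
dcp   <- generate_vessel_network(angio_scene_params(plexus = "DCP", seed = 43))
rec <- compute_metric_record(scene$image, dcp$image,
                             scene$faz_polygon, dcp$faz_polygon)
print(rec, digits = 3)
#>   participant_id  eye vd_scp vd_dcp fd_scp fd_dcp pd_large_scp faz_area_scp
#> 1           <NA> <NA>   10.9   9.88   1.47   1.39         7.02         0.31
#>   faz_area_dcp signal_strength_scp signal_strength_dcp
#> 1         1.11                   8                   8
```

`vd_scp = 10.9` mm/mm² is the skeleton length per unit area inside the
annulus (the default synthetic mesh is sparser than a real plexus, so this
sits below clinical values); `pd_large_scp = 7.02`% is the areal fraction
of detected large vessels; the FAZ areas recover the generator's targets
(0.31 and 1.11 mm²) exactly because the polygon is part of the truth.

```r
# a synthetic 90-participant cohort with planted group deficits
cohort <- generate_cohort(cohort_params(seed = 1))$cohort
fit <- fit_adjusted_model(cohort, "vd_scp")
print(fit)
#> <adjusted_model_result> outcome vd_scp, n = 90
#>     group adjusted_mean     se raw_sd  n
#> 1 control         15.07 0.2198 1.0550 29
#> 2     MCI         14.56 0.1739 0.9885 37
#> 3      AD         14.96 0.2521 1.3167 24
#>   group estimate ci_lower ci_upper p_value
#> 1   MCI  -0.5117  -1.0773  0.05379 0.07551
#> 2    AD  -0.1116  -0.8557  0.63243 0.76607
```

At this cohort size a planted AD deficit of −0.88 is often not
significant in a single draw — exactly the situation the post hoc power
calculation quantifies; across replicates the 95% CI covers the planted
value at the nominal rate (see `tests/testthat/test-acceptance.R`).

The three pipeline stages are also scriptable from a shell:

```sh
Rscript inst/cli/octaquant.R simulate --config config.yaml --out fixtures/
Rscript inst/cli/octaquant.R metrics  --config config.yaml --in fixtures/ --out metrics.csv
Rscript inst/cli/octaquant.R stats    --config config.yaml --metrics metrics.csv \
        --cohort fixtures/cohort.csv --out results/
```

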