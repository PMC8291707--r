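# crvtoffset

Geometric measurement of **central retinal vascular trunk (CRVT) offset**
from the Bruch's membrane opening (BMO) centre, and the paired-eye
statistical pipeline built on it.

## The problem

In unilateral normal-tension glaucoma (NTG), one eye of a patient is
damaged while the fellow eye — sharing every systemic risk factor — is
not. A candidate explanation is loco-regional: the lamina cribrosa (the
collagenous sieve the optic nerve axons pass through) can be dragged away
from the BMO centre during eye growth, and the emergence point of the
central retinal vessels (the CRVT), which is embedded in the lamina,
records that displacement. `crvtoffset` is for researchers who delineate
BMO margins and CRVT landmarks on OCT imaging and want to quantify that
displacement and analyse it in a matched paired-eye design.

## The statistic

For a delineated BMO margin polygon with area centroid $C$:

* **offset index** $= a/b$, where $a$ is the distance from $C$ to the
  CRVT and $b$ the distance from $C$ to the BMO margin along the same
  ray; $a/b \in [0,1]$, with 1.0 assigned when the trunk lies outside
  the BMO;
* **angular deviation** $\alpha$: direction of the trunk from $C$ in
  right-eye orientation (nasal midline $0^\circ$, superior positive);
  left-eye records are mirrored first;
* **RNFL defect angle** $\beta$: circular midpoint of a nerve-fibre-layer
  defect on the margin, temporal midline $0^\circ$, the wider defect
  when there are two.

Downstream, the package implements the full inference chain of a
paired-eye study: paired *t*/Wilcoxon comparisons, matched-pair
conditional logistic modelling with a p < 0.20 univariable screen, a
linear GEE of offset index on diagnosis and cubic axial-length terms with
exchangeable within-pair correlation and sandwich CIs, LOESS curves,
closed-form cubic minimisation, and CRVT/RNFL angle correlations. A
calibrated synthetic cohort generator (group moments, generative cubic,
pair correlations, exclusion cascade) lets every stage run with no
patient data. See the vignette `vignettes/crvt-offset-methods.Rmd` for
the model and every numerical choice.

## Worked example

```r
library(crvtoffset)

# one synthetic eye, measured back through the geometry engine
eye <- synthesize_eye_geometry(target_index = 0.5, target_angle_deg = 30,
                               laterality = "OD", bmo_area = 2.7, seed = 7)
measure_crvt(eye)
#> CRVT measurement
#>   offset index       : 0.5000
#>   angular deviation  : +30.00 deg
#>   BMO area           : 2.700 mm^2
#>   flags              : none
```

The offset index is recovered exactly (the CRVT was placed halfway along
the ray at $+30^\circ$), and the margin polygon was scaled to exactly
2.7 mm².

```r
# a complete synthetic study: generate 112 patients, measure every eye,
# apply the screening cascade, run all analysis stages
report <- run_pipeline(run_config("synthetic", out_dir = "crvt_run", seed = 42))
#> [crvtoffset] synthetic mode: 112 patients, seed 42
#> [crvtoffset] generated 224 eyes
#> [crvtoffset] measured 224 eyes through the geometry engine
#> [crvtoffset] exclusions: poor_quality=7, bifurcation=6,
#>   invisible_no_angio=3, outside_both_eyes=3 (total 19); 14
#>   invisible-confirmed retained
#> [crvtoffset] analysing 93 patients
#> [crvtoffset] GEE argmin at 23.62 mm (none)

read.csv("crvt_run/table3.csv")[, c("term", "estimate", "p")]
#>             term  estimate        p
#> 1    (Intercept)  1.20e+01 6.68e-01
#> 2      diagnosis  2.22e-01 3.43e-14
#> 3   axial_length -9.87e-01 7.74e-01
#> 4 axial_length^2  2.08e-02 8.82e-01
#> 5 axial_length^3  2.21e-06 9.99e-01
```

On this run the glaucoma eyes carry a significantly larger offset index
than their fellow controls (diagnosis coefficient ≈ 0.22 — the generative
0.158 plus the contribution of the fourteen outside-BMO eyes forced to
1.0 by the screening stage), the cubic axial-length terms are individually
noisy at n = 93 (as expected for a near-collinear polynomial basis), and
the fitted curve's minimum lands at 23.6 mm. `table1.csv`, `table2.csv`,
`fig2_loess.csv`, `angle_correlations.csv` and a JSON run report with the
exclusion tally, seed and calibration checksum are written alongside.

A thin command-line front end with `simulate` / `measure` / `analyse` /
`show-config` subcommands is installed at `inst/cli/crvt_pipeline.R`.

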