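# macvasc

Morphometry of the macular vascular network from binarized fundus vessel
maps, and eye-clustered statistics for paired-eye cohorts.

`macvasc` is for researchers who already have binary vessel segmentations
of the macula (from any segmentation method) and need (a) standardized
per-sector geometric measurements and (b) population-level sex/age
inference that respects the correlation between the two eyes of each
subject.

## What it computes

**Per eye**, on a fovea-centered ETDRS grid (circles of 1, 3 and 6 mm
diameter; inner and outer rings split into superior / inferior / nasal /
temporal quadrants; the central 1 mm excluded), for each of the 8 quadrant
sectors and the inner-ring / outer-ring / whole composites:

- **D_f** — box-counting fractal dimension of the vessel skeleton,
  the slope of log N(ε) against log(1/ε) over dyadic box sizes;
- **VAR** — vessel area rate, the exact fraction of region pixels occupied
  by vessel;
- **D_m** — mean vessel diameter in mm, twice the distance-transform
  half-width averaged over skeleton pixels;
- **τ** — subdivision tortuosity: the maximum over dyadic subdivision
  levels of the summed absolute chord turning angles, scaled by a sigmoid
  `g(m) = 2/(1+e^(−m/2))` of the curvature-sign inflection count *m*,
  aggregated per region as an arclength-weighted mean.

**Per cohort**, marginal linear models fitted by generalized estimating
equations with identity link, exchangeable working correlation
(cluster = subject) and robust sandwich variance:

    E[y_ij] = β0 + β_sex·male_i + β_age·age_i,   Corr(y_i1, y_i2) = α

with Wald z inference and β ± 1.96·SE intervals, plus sex-difference and
age-association reports per metric × region, pairwise age-group contrasts
adjusted for sex, baseline mean ± SD tables, summary-statistic t tests
(pooled and Welch), a chi-square sex-ratio test and Shapiro–Wilk.

Synthetic generators — branching Murray-law vessel trees with a foveal
avascular zone, and paired-eye cohort tables with configurable sex/age
effects and intereye correlation — make the full pipeline testable with no
external data.

## Worked example

```r
library(macvasc)

## one synthetic eye: grid -> vessel map -> per-region metrics
spec <- grid_spec(fovea_center = c(101, 101), scale_mm_per_px = 0.03,
                  laterality = "OD", image_shape = c(201, 201))
vm <- generate_tree_image(tree_params(seed = 7), spec)
quantify(vm, regions = c("inner_ring", "outer_ring", "whole"))
#>      region    Df    VAR      Dm    tau
#>  inner_ring 1.236 0.1585 0.04076 0.7466
#>  outer_ring 1.222 0.1055 0.04236 0.9468
#>       whole 1.323 0.1175 0.04184 0.9458
```

A fractal dimension of ~1.3 says the skeleton fills space at a rate between
a curve and a surface; VAR 0.12 means 12% of the analysed area is vessel;
D_m is in mm (≈ 1.4 px at this scale per half-width); τ is this package's
tortuosity scale (comparable within, not across, tortuosity definitions).

```r
## a synthetic 305-subject, 610-eye cohort and the eye-clustered GEE
tab <- generate_cohort(cohort_params(n_subjects = 305), seed = 1)
fit <- gee_exch(Df_whole ~ sex + age_years, tab, id = "subject_id")
summary(fit)
#> Gaussian GEE (identity link, exchangeable working correlation)
#> 610 eyes / observations in 305 clusters; working correlation alpha = 0.5423
#>
#>                Estimate   Robust SE    CI lower    CI upper        z  Pr(>|z|)
#> (Intercept)  1.41287558  0.00610757  1.40090474  1.42484643 231.3317 < 2.2e-16
#> sexM         0.01286481  0.00366914  0.00567329  0.02005633   3.5062 0.0004545
#> age_years   -0.00089923  0.00012550 -0.00114521 -0.00065325  -7.1652 7.765e-13
```

The cohort was generated with a true male–female difference of 0.010 and a
true age slope of −9.812×10⁻⁴ per year for whole-macula D_f; the fit
recovers both within its robust confidence intervals, with the estimated
working correlation α ≈ 0.54 close to the generating intereye correlation
of 0.5. Table-style reports come from the analysis wrappers, e.g.

```r
sex_difference_analysis(tab, metrics = "Df", regions = "whole")
#>   metric region       beta    ci_lower   ci_upper           p
#> 1     Df  whole 0.01227284 0.004461287 0.02008439 0.002074293
```

For file-based work, `read_vessel_map()` / `write_vessel_map()` handle
PNG/TIFF masks with JSON sidecars (fovea, scale, laterality),
`write_fixture_set()` emits a small synthetic eye set, and
`run_pipeline()` drives images → metrics CSV → statistical reports with a
seed-stamped manifest.

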