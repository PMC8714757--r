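---
title: "Quantifying macular vascular geometry and its sex and age effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macular vascular geometry and its sex and age effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macvasc)
```

## The problem

The macular microvasculature — the capillary network around the fovea — is
one of the few vascular beds visible non-invasively, and its geometry shifts
with sex, age and early microvascular disease. Given a *binarized* vessel
map of the macula (segmentation itself is out of scope here: the package
consumes masks, from any segmentation method), `macvasc` answers two
questions:

1. **Morphometry.** How space-filling, dense, wide and tortuous is the
   vessel network in each ETDRS sector of one eye?
2. **Population inference.** Across a cohort where *both* eyes of each
   subject are measured, how do those metrics vary with sex and age, with
   the intereye correlation handled correctly?

Because both eyes of a subject are strongly correlated, naive per-eye
regression understates uncertainty. The package fits marginal linear models
by generalized estimating equations (GEE) with an exchangeable working
correlation (cluster = subject) and robust sandwich standard errors — the
standard design for paired-eye ophthalmic data.

## The ETDRS partition

The grid is built in pixel space from a physical specification: fovea
position, mm-per-pixel scale and laterality. Three fovea-centered circles of
diameter 1, 3 and 6 mm define a central zone, an inner ring
(0.5–1.5 mm radius) and an outer ring (1.5–3 mm), each ring split into
superior / inferior / nasal / temporal quadrants by the two ±45° diagonals
through the fovea.

Numerical conventions, chosen for unambiguous tiling and determinism:

* radial bands are half-open `[inner, outer)` on the pixel-center distance;
* pixels exactly on a diagonal go to the vertical (superior/inferior)
  quadrants;
* row 1 is the top of the image and "superior" is up; for a right eye (OD)
  the nasal retina is on the image's right, for a left eye (OS) on the left.
  Camera mirroring conventions vary, so `nasal_side` can override this;
* the central 1 mm circle — essentially the foveal avascular zone — is
  labeled but excluded from every analysis region, and the "whole" region is
  the union of the two rings only;
* the input raster is never resampled; masks are computed at its native
  resolution.

```{r grid}
spec <- grid_spec(c(101, 101), 0.03, "OD", c(201, 201))
grid <- build_grid(spec)
sum(grid$masks$inner_ring) / sum(grid$masks$outer_ring)  # ~ 8/27
```

## The four metrics

All metrics are computed per region from the mask and a centerline graph
obtained by topology-preserving thinning (Zhang–Suen), with per-centerline
half-widths from the Euclidean distance transform and terminal spurs
shorter than 5 px pruned — standard morphometry practice.

**Fractal dimension `Df`.** Box counting on the skeleton points inside the
region: box sides 2, 4, 8, … px up to a quarter of the longer side of the
region bounding box, grid anchored at the bounding-box origin (one fixed
offset, no offset averaging — deterministic and simple; offset averaging
could be added without changing the interface). `Df` is the least-squares
slope of log N(ε) on log(1/ε); with fewer than four usable scales or no
points the metric is flagged undefined rather than reported as a number.

**Vessel area rate `VAR`.** The exact integer-count fraction of region
pixels that are vessel; no estimation involved.

**Mean diameter `Dm`** (mm). Twice the half-width averaged over skeleton
pixels in the region — averaging per pixel rather than per segment makes
the mean length-weighted automatically. The half-width at a skeleton pixel
is the distance-transform value minus half a pixel (so a 5-px-wide bar
reads exactly 2.5 px); when thinning had to place the centerline on one of
two equal-distance pixel rows (even widths), an off-skeleton neighbor with
an equal or larger distance marks the case and half a pixel is added back.
This keeps constant-width test vessels of widths 3–15 px within one pixel
of truth.

**Tortuosity `tau`.** Segment paths are clipped to their maximal in-region
sub-paths (clipping, rather than majority assignment, avoids double
counting across sectors), resampled by arclength, and scored by dyadic
subdivision: at level *k* the path becomes 2^k equal-arclength chords and
the absolute turning angles are summed; the base score is the maximum over
levels `k = 1..K`, `K = min(6, floor(log2(L/4)))` with a floor of one level
so every eligible path (≥ 4 px) is scored. The base score is multiplied by
`g(m) = 2/(1 + exp(-m/2))` where *m* counts curvature-sign inflections
along the finest-level chords — an inflection-free arc is unpenalized
(`g(0) = 1`) and the factor saturates at 2. A region's `tau` is the
arclength-weighted mean over eligible sub-paths. The exact functional form
of subdivision tortuosity varies between implementations in the literature;
the definition above is fixed here for reproducibility, and its *absolute*
scale is therefore specific to this package — comparisons should rely on
its ordering and invariance properties (zero iff straight, monotone in
amplitude and inflection count, invariant to reversal and rigid rotation),
which the test suite asserts.

## The synthetic generators

No public image set accompanies the cohort this design targets, so the
package ships two generators that make every stage testable from code.

**Vessel trees.** `generate_tree_image()` grows stochastic branching trees
from entry points on the 6 mm circle toward the fovea: sinusoidal
centerline perturbation (amplitude/wavelength dials), Murray-law caliber
tapering (child = parent × 2^(−1/3) by default), disc-stamped
rasterization, and a vessel-free foveal avascular zone (0.3 mm radius
default). Defaults (5 roots, branching 0.5/mm, 0.07 mm trunks) were chosen
once to give realistic binarized-fundus geometry — whole-macula vessel
area fraction near 0.1, fractal dimension near 1.3–1.5 — and the dials are
monotone in their target metrics (density → VAR, branching → Df, trunk
caliber → Dm, wiggle amplitude → tau), verified by `calibration_curve()`.
What the generator does *not* emulate: arcade anatomy, artery/vein
duplexes, segmentation noise and breaks, or background artifacts. Passing
geometry tests on these trees validates the measurement code, not any
claim about real fundus photographs.

**Cohorts.** `generate_cohort()` draws eye-level metric tables directly
from a linear mixed structure: `value = b0 + b_sex·male + b_age·age +
b_subject + e_eye`, with the subject effect shared by both eyes. Defaults
use the published sex and age coefficients for healthy macular vasculature
as ground truth (e.g. whole-macula fractal dimension: +0.010 male–female,
−9.812×10⁻⁴ per year; tortuosity: zero effects), total SDs matching the
published per-metric SDs, intereye correlation 0.5 (an assumption — the
source tables report no variance decomposition — surfaced as
`intereye_cor`), and ages uniform on 18–70 (the study population skews
young; the uniform default identifies the age slope better and is
configurable). Simulating cohorts at the metric level rather than through
images is deliberate: the dial → metric map of the tree generator is
monotone but not analytically invertible, so image-level cohort simulation
would not admit exact ground-truth coefficients.

## The GEE

`gee_exch()` is a classic formula + data fitting function returning a
classed object with `print`, `summary`, `coef`, `vcov`, `confint`,
`predict`, `residuals`, `fitted` and `plot` methods. It implements the
Gaussian identity-link GEE with exchangeable working correlation directly:
the correlation parameter comes from the moment estimator on standardized
residuals (clamped to the valid range), coefficient updates use the
closed-form Woodbury inverse of the exchangeable correlation per cluster,
and the two steps alternate to a 1e−8 coefficient tolerance (max 100
iterations; non-convergence warns and flags the fit). Inference is robust
throughout: sandwich covariance, z-based Wald tests and `β ± 1.96·SE`
intervals, with no small-sample correction. Two exact reductions anchor
the implementation in the tests: with one observation per cluster it
reproduces OLS with HC0 errors, and with balanced paired clusters and
cluster-constant covariates it reproduces OLS with cluster-robust (HC0,
unadjusted) errors — both checked against independent reference routines.

```{r gee}
tab <- generate_cohort(cohort_params(n_subjects = 305), seed = 1)
summary(gee_exch(Df_whole ~ sex + age_years, tab, id = "subject_id"))
```

The analysis battery mirrors a complete cross-sectional report:
`sex_difference_analysis()` (sex as sole covariate, per metric × region),
`age_association_analysis()` (age continuous), `age_group_comparison()`
(groups ≤25 / 26–35 / 36–45 / ≥46 on floored ages, sex as covariate, all
six pairwise Wald contrasts), `baseline_table()` (mean ± SD per
sex × group stratum), plus `t_test_from_summary()` (pooled and Welch — the
demographic contrasts of the source design reconcile with eye-level counts,
pooled for three groups and Welch for one, so both variants are exposed),
`chi_square_sex_ratio()` and `shapiro_wilk()`. No multiple-testing
correction is applied by default, matching common practice in the source
literature; `age_group_comparison(adjust = "bonferroni")` or `"holm"` opts
in. Significance is two-sided at 0.05.

## Numerical choices and degenerate inputs

* Undefined metrics (empty region, no skeleton, too few box scales) are
  explicit `defined = FALSE` flags, never 0 — 0 is a legal value for VAR
  and tau.
* An empty vessel mask yields a flagged-empty graph, not an error; an empty
  *region mask* is a validation error.
* Zero-variance t-tests return statistic 0 for equal means and a flagged
  infinity otherwise.
* Sandwich variances can round to tiny negatives in near-degenerate designs
  (more parameters than clusters); they are clamped at zero before square
  roots.
* All generators are pure functions of their seed; the pipeline manifest
  records the seed and a config hash.

## Problem sizes

The test suite and the acceptance script run at deliberately modest sizes
chosen to exercise every code path with tight Monte-Carlo error: 201×201 px
rasters at 0.03 mm/px for image geometry, 50 replicate cohorts of 305
subjects × 2 eyes for parameter recovery (Monte-Carlo SE ≈ 1.6×10⁻⁵ on the
fractal-dimension age slope, under 2% of the effect), and 1,000+ subjects
where correlation recovery is asserted.

## Known limitations

* Tortuosity values are not comparable across packages (see above).
* Box counting uses a single grid offset; offset averaging would reduce
  small-sample bias at the cost of determinism of the published values.
* Even-width vessels are handled by the half-pixel plateau rule, which can
  add up to half a pixel near junctions; all caliber guarantees are ±1 px.
* The cohort generator's intereye correlation and variance split are
  assumptions, not estimates.
* Artery/vein discrimination and vessel segmentation are out of scope.
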