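---
title: "Effective disc age: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective disc age: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discage)
```

## The problem

Lumbar intervertebral discs degenerate with normal aging, and they do so at
different rates at different spine levels. Conventional degeneration grades
(ordinal scales read off T2-weighted images) ignore both facts, which makes
it impossible to say whether a given disc is merely *as old as its owner*
or degenerating *faster than aging alone would explain*. The quantity this
package computes, the **effective disc age**, is the age at which normal
aging would, on average, produce a disc's observed phenotype. Comparing it
with the subject's true age splits degeneration into an expected,
age-driven part and an excess part:

* effective age ≈ true age: normal aging;
* effective age − true age > threshold: *accelerated degeneration*.

## The scoring model

For each lumbar level $\ell \in \{$L1-L2, …, L5-S1$\}$ the effective age is
a linear function of four MRI-derived predictors,

$$\widehat{A}_\ell = \beta_{0,\ell}
  + \beta_{T2,\ell}\,T2_{NP}
  + \beta_{H,\ell}\,H
  + \beta_{A,\ell}\,A_{ms}
  + \beta_{V,\ell}\,V,$$

with $T2_{NP}$ the nucleus pulposus T2 relaxation time (ms), $H$ the
subject's standing height (inches), $A_{ms}$ the mid-sagittal disc area
(mm²) and $V$ the 3D disc volume (mm³). The packaged coefficients
(`default_coefficients()`, stored as JSON in `extdata/`) are frozen
per-level values together with each level's fit $R^2$ and residual RMSE in
years:

```{r}
default_coefficients()
```

Scoring is exactly linear, so a unit finite difference in any predictor
recovers its coefficient — the property the test suite uses to verify that
the packaged document is encoded faithfully *through the computation*, not
by re-reading the JSON.

**Classification threshold.** The boundary between "normal" and
"accelerated" is not part of the frozen model, so a choice was needed. The
default classifies a disc as accelerated when
$\widehat{A} - A > \mathrm{RMSE}_\ell$ (strict inequality; the level's own
model RMSE is the natural error scale for its predictions), and
symmetrically as younger-than-expected below $-\mathrm{RMSE}_\ell$. Both
the policy (`threshold_policy`) and the value (`threshold_years`) are
configurable. Effective ages outside the 18–83-year development range are
reported unclipped, with a flag: clipping would mask exactly the extreme
discs the model exists to find.

**Units.** Heights are accepted in inches or centimetres behind an
explicit `height_units` flag (internal canonical unit: inches, because the
height coefficient is per inch). There is no unit guessing.

## T2 relaxometry

The nucleus T2 time comes from a multi-echo CPMG acquisition of the
mid-sagittal slice — by default 25 echoes at multiples of 13.6 ms, up to
340 ms. The signal analysed is the mean magnitude over a circular nucleus
ROI (one fit per ROI, not per-voxel fits averaged), typically 80–120
voxels; sizes outside that range are flagged.

Magnitude MRI data do not decay to zero: rectified complex noise leaves a
positive floor, and a naive exponential (or log-linear) fit therefore
overestimates T2, increasingly so at low SNR. The canonical noise-corrected
single-exponential used here is

$$S(TE) = \sqrt{(S_0 e^{-TE/T_2})^2 + C^2},\qquad S_0 > 0,\ T_2 > 0,\ C \ge 0,$$

i.e. the noiseless decay added in quadrature with a constant floor $C$.
The plain exponential remains available via `model = "exponential"`, and
`fit_t2_loglinear()` implements the uncorrected baseline; a Monte-Carlo
test verifies that the corrected fit has smaller bias than the log-linear
fit on Rician-corrupted decays at SNR 30 and 50.

Numerical choices for the fit:

* Levenberg–Marquardt least squares (`minpack.lm::nls.lm`) under the bound
  constraints above;
* multi-start initialization with $T_2 \in \{20, 50, 100, 200\}$ ms, $S_0$
  at the first-echo intensity and $C$ at the last-echo intensity, keeping
  the lowest-residual solution — this avoids local minima without
  introducing any seed dependence;
* relative parameter tolerance $10^{-8}$, at most 1000 iterations;
* non-decaying or constant signals are reported as `converged = FALSE`
  with a reason, never as extrapolated parameters.

**Regional analysis.** Regional T2 partitions the anterior–posterior
extent of the masked disc (measured at the mid-height of the mask in the
mid-sagittal slice) into five contiguous bands: anterior annulus (AAF),
anterior transition (Atrans), nucleus (NP), posterior transition (Ptrans)
and posterior annulus (PAF). The default cut fractions
(0.15, 0.30, 0.70, 0.85) give 15 %-wide annulus bands, 15 %-wide
transitions and a 40 %-wide nucleus; they are a package default chosen for
symmetry and plausibility — not a published partition — and are fully
configurable. Each band's mean masked decay is fit with the same
noise-corrected model; an empty band yields a flagged `NA`, not an error.

## Disc morphometry

All geometry works in physical units on a canonical orientation (axis 1
anterior, axis 2 superior, axis 3 left–right) declared per image with
`axis_convention()`; nothing is inferred from NIfTI headers beyond voxel
spacing.

* **Volume**: segmented voxel count × unit voxel volume.
* **Mid-sagittal area**: segmented voxel count in the mid-sagittal slice ×
  unit in-plane area.
* **Width**: anterior–posterior span of the mask at *mid-height*, defined
  as the midpoint of the mask's superior–inferior pixel extent (not the
  centroid row — the midpoint is deterministic and robust to asymmetric
  bulge). An empty mid-height row falls back to the nearest nonempty row,
  flagged.
* **Height**: the disc interspace is the quadrilateral through the four
  vertebral-body fiducials (upper-anterior, upper-posterior,
  lower-posterior, lower-anterior); height = shoelace area / interspace
  width, where the interspace width is the mean of the upper and lower
  fiducial segment lengths. This definition is symmetric and reduces to
  the obvious width for rectangular interspaces; for a trapezoid with
  parallel vertical sides of 8 and 12 mm spanning 40 mm it gives
  $400/\sqrt{40^2+2^2} = 9.99$ mm rather than exactly 10, because the
  tilted fiducial segments are slightly longer than their horizontal
  projection.
* **Bulge**: masked in-plane area strictly anterior of the (infinite) line
  through the two anterior fiducials, and strictly posterior of the
  posterior line. Voxels are classified by the signed distance of their
  centre, half-open: centres exactly on a line count as inside the
  interspace. Pixel counting is used rather than sub-pixel polygon
  clipping, matching the voxel-counting definitions of area and volume.
* **Wedge angle**: the signed angle between the upper and lower fiducial
  segments, computed as the difference of their posterior-to-anterior
  directions; positive when the interspace opens anteriorly (lordotic
  wedge — the sign convention is ours, chosen so normal lumbar wedges are
  positive). It is invariant under common rigid rotations of all four
  markers.

Accuracy is validated against analytic phantoms: a digitized
20 × 5 × 15 mm ellipsoid reproduces its closed-form volume and mid-sagittal
area within 2 % at 0.5 mm voxels. The refinement study (1.0 → 0.5 →
0.25 mm, errors strictly decreasing) uses a 19.7 × 5.3 × 14.9 mm ellipsoid:
integer-millimetre semi-axes are commensurate with the voxel lattice and
can produce exact error plateaus (the 20 × 5 × 15 count at 0.25 mm is
exactly eight times its 0.5 mm count), which says something about grid
alignment, not about the measure.

## Model development

`fit_level_model()` fits ordinary least squares of true age on any
predictor set, independently per level, with listwise deletion of
incomplete rows (counts logged). Reporting conventions:

* $R^2 = 1 - SSE/SST$;
* RMSE $= \sqrt{SSE/(n-p-1)}$ by default — the residual-degrees-of-freedom
  convention used by the major commercial statistics packages whose output
  such coefficient tables are reported in — with `rmse_denominator = "n"`
  available;
* standardized betas $\beta^{std}_j = b_j\,s_{x_j}/s_y$ (equal to the
  Pearson correlation for a single-predictor model);
* VIF$_j = 1/(1-R^2_j)$ from regressing predictor $j$ on the others;
  a single predictor has VIF 1, perfect collinearity reports `Inf`;
* two-sided $t$-test p-values per coefficient, uncorrected (reported for
  completeness; no multiplicity correction is applied because none is part
  of the workflow being mirrored).

`all_subsets_search()` enumerates *every* subset of sizes
{1, 2, 4, 6, 8} (up to $\binom{16}{8} = 12870$ subsets per size — brute
force is the specification here, and a test checks the bookkeeping against
an independent enumeration). Because "considering all discs
simultaneously" can be read several ways, the default pooling fits each
subset per level and averages $R^2$ across the five levels
(`criterion = "rmse"` averages RMSE instead); criterion ties break towards
the lexicographically smallest predictor-name set, so results are
reproducible to the byte.

`kfold_cv()` shuffles a level's rows under a mandatory seed, deals them
round-robin into five folds (sizes differing by at most one — 84 rows give
17/17/17/17/16), fits on each four-fold complement and records the
validation RMSE on the held-out fold. The reported model uncertainty is
half the range of the five fold RMSEs, and the seed is part of the report.

## The synthetic cohort generator

No subject-level data are distributed with the package, so every
end-to-end claim is validated on synthetic cohorts with known ground
truth. The generator (`cohort_spec()` / `generate_cohort()`) emulates the
study design the model came from: 84 subjects, ages drawn uniformly over
18–83 years, sex balanced (recorded but effect-free), five lumbar levels
per subject.

Generation is *predictor-first*: each predictor is drawn from a
level-specific conditional mean that is linear in a latent subject age
(nucleus T2 falling with age and toward inferior levels; area and volume
growing with age and toward inferior levels; disc height falling and
width/bulge/wedge rising with age; annulus T2 rising with age), plus
Gaussian scatter. The recorded age of each disc row is then *regenerated*
from the planted coefficient set as
$\mathrm{age} = \beta_0 + \sum_j \beta_j x_j + \varepsilon$,
$\varepsilon \sim N(0, 8.8\ \mathrm{yr})$, clipped to the age range with
the clip count logged. Regeneration makes the forward model's coefficients
exact by construction, so refitting is a genuine parameter-recovery
experiment.

Three generator design choices deserve explanation:

* **Score-to-age calibration.** The conditional-mean slopes are calibrated
  so that the planted linear score rises at `signal_slope` (default 0.45)
  years of effective age per year of latent age and is centred mid-range;
  the volume age-slope is solved per level from the planted coefficients
  to achieve this for *any* coefficient set. The compression keeps the
  regenerated ages almost entirely inside 18–83: range-clipping is the one
  mechanism that biases coefficient recovery, and under the defaults it
  touches well under 2 % of rows. The residual effect is a small shift
  concentrated in the intercept (on the order of one year) with
  sub-percent attenuation of the slopes.
* **Allometric predictor coupling.** Disc area and volume scale with
  stature (`area_height_slope`, `volume_height_slope`) and volume with the
  non-stature part of area scatter (`volume_area_slope`), as disc
  dimensions do in vivo. Besides realism, this coupling matters
  statistically: with a negative height coefficient and a positive volume
  coefficient, positively correlated scatter partially cancels in the
  planted score, which is what keeps regenerated ages in range without
  shrinking the marginal variances to implausible values.
* **Per-row ages.** Because the forward model is planted per level, the
  regenerated "true age" is disc-specific; per-level fits (the only fits
  the workflow performs) never see the discrepancy between a subject's
  rows.

`inject_accelerated_discs()` shifts every age-trended predictor of a
seeded row subset to its conditional-mean value at (age + `excess_years`),
leaving the recorded age unchanged and marking the rows — ground truth for
sensitivity/specificity of the delta-threshold classifier. Under the
defaults, +25 years of excess phenotype age shifts the expected delta by
`signal_slope` × 25 ≈ 11 years against an 8.8-year noise SD, so detection
at the L3-L4 RMSE threshold runs near 60 % at a ~10 % false-positive rate
— far above chance, but deliberately not a clean separation: excess
degeneration of the same order as the model error should look hard.

`generate_phantom()` supplies the imaging-side test double: a voxelized
ellipsoid (a voxel is inside if its centre satisfies the ellipsoid
equation) with five-band T2 layout, mono-exponential per-voxel signal,
optional Rician corruption (`rician_noise()`, the exact
two-channel-Gaussian magnitude model), and fiducials bounding a
trapezoidal interspace with closed-form height and wedge angle.

**What the synthetic data do not emulate:** measurement error in the
predictors (segmentation variability, ROI placement), non-Gaussian or
heteroscedastic age residuals, intra-subject correlation across levels,
bias fields, motion, or any relation between Pfirrmann-style grades and
the generated quantities. Passing the recovery tests therefore
demonstrates that the *pipeline* is correct and well-calibrated — not that
the frozen coefficients are accurate for any real population.

## Problem sizes used by the test and acceptance runs

Chosen to make every stochastic check stable at comfortable margins:
noiseless fits are checked to 1e-6 relative; the Rician relaxometry Monte
Carlo uses 200 repeats at SNR 50 (plus 100 at SNR 30); phantom refinement
runs at 1.0/0.5/0.25 mm; the generator/fitter loop uses 200 cohorts of
84 subjects for bias and error-scale checks and 10 cohorts for detection
rates; the acceptance script reports means over 20 cohorts.

## Known limitations

* The noise-correction model and the five-band partition are canonical
  choices, not a reimplementation of any specific acquisition's published
  supplementary definitions; both are configurable.
* The packaged coefficients were developed on asymptomatic adults aged
  18–83; applying them to symptomatic or out-of-range populations is
  extrapolation, and the package deliberately reports (rather than clips)
  out-of-range effective ages.
* Bulge areas use pixel counting, so their precision is one pixel row
  along the fiducial line.
* The delta threshold equal to the level RMSE is a pragmatic default; the
  width of the "normal aging" band is a modelling decision the user can
  override.
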