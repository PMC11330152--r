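---
title: "Evaluating delivered dose in lung SABR with adaptive CTs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating delivered dose in lung SABR with adaptive CTs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In stereotactic ablative radiotherapy (SABR) for lung tumours, a plan is
optimized once on a planning CT (PCT) and then delivered over a few
fractions. At each fraction the patient is set up under cone-beam CT (CBCT)
guidance, but residual setup error and day-to-day anatomic deformation mean
the dose actually absorbed by the target can differ from the plan. A common
way to estimate the *delivered* dose is to build, for every fraction, an
adaptive CT (ACT): the PCT rigidly aligned with the recorded couch
correction and then deformably registered onto the daily CBCT. The target
structures are propagated through the resulting deformation vector field
(DVF), the fraction dose is computed on the ACT, warped back into the
planning frame through the inverse map, and the per-fraction doses are
averaged into a delivered-dose estimate per tissue element.

`actdose` implements this whole chain on synthetic phantom cohorts, plus the
statistics layer used to ask *what drives the delivered PTV D95%*: stepwise
multiple linear regression with collinearity diagnostics, a high-ΔHI
subgroup refit, studentized-residual outlier flagging, and one-way ANOVA of
the target parameters by lung lobe.

## Geometry and containers

All grids are axis-aligned in a world frame in mm, voxel centers at
`origin + index * spacing` (0-based indices). Three containers cover every
stage: `volume_grid` (CT in HU, dose in cGy), `binary_mask` (ITV/PTV and
their propagated counterparts) and `displacement_field` (mm 3-vectors under
the fixed-frame pull-back convention: fixed-frame point `x` maps to
moving-frame point `x + u(x)`). Sampling outside a grid returns a
role-specific fill: 0 for dose and masks, −1000 HU for CT. Oblique
orientations are deliberately unsupported — the synthetic data is
axis-aligned and this keeps resampling exactly invertible on identical
geometries. Dose is carried in cGy throughout (the prescription 60 Gy is
stored as 6000 cGy) so regression coefficients are on the scale clinicians
print.

## The synthetic cohort

No clinical volumes ship with the package; the generator *is* the data
source, and it is first-class, tested code. A cohort
(`cohort_config()`) fixes the study conditions:

* 72 patients, four CBCT-guided fractions each — 288 ACT cases; patients are
  assigned to lung lobes in the reference proportions (21 LUL, 15 LLL,
  16 RUL, 4 RML, 16 RLL).
* Each phantom is a smooth "body" ellipsoid of soft tissue containing two
  low-HU lungs with Gaussian vessel-like texture (so the registration has
  intensity gradients away from the tumour), and an ellipsoidal ITV
  (semi-axes 7–13 mm) at a lobe-dependent seed position. The PTV is the
  Euclidean dilation of the ITV by a per-patient margin drawn from 5–7 mm.
  Lobe geometry is schematic: only the lobe *label* and its motion
  amplitude matter to the analysis.
* Per fraction, a residual rigid setup error (translation, SD 1.2 mm per
  axis — a realistic post-CBCT-correction residual) and a random cubic
  B-spline ground-truth deformation (control spacing 30 mm). The field is
  scaled so its mean displacement magnitude over the PTV matches the
  patient's lobe amplitude, jittered per fraction (SD 55% of the amplitude,
  floored at 10%); amplitudes follow the reference per-lobe means
  (1.51–2.47 mm, larger in the lower and middle lobes). Fields are capped
  at 12 mm peak displacement and never fold (positive Jacobian, which the
  tests assert). The CBCT-like fixed image is the PCT resampled through the
  total map plus 10 HU Gaussian noise.
* The reference plan is an analytic stand-in for the treatment planning
  system: a uniform spherical dose core at the isocenter with radius equal
  to the PTV equivalent-sphere radius and a Gaussian penumbra (σ = 5 mm,
  giving a 100%→50% falloff over ≈ 6 mm, typical of lung SABR), scaled so
  the planned PTV D95% equals 6000 cGy exactly.

Two grid profiles exist: `fast` (64³ voxels at 2.5 mm) and `fine` (128³ at
1.25 mm). All shipped analyses, tests and the acceptance script use the
fast profile; a full 72-patient evaluation takes about ten minutes on one
CPU there.

Every generator is a pure function of `(config, seed)`: the global seed is
expanded into per-patient and per-fraction substreams by a stable integer
hash, so results are reproducible independently of evaluation order, and a
`cohort.json` round-trip reproduces a run bit-identically.

### What the generator does and does not emulate

It emulates the *structure* of the clinical problem: lobe-dependent motion
amplitude ordering, four-fraction repetition, margin-based target design,
a D95-normalized prescription, and registration-recoverable smooth
deformations. It does not emulate CT texture, CBCT scatter or artifacts,
4DCT/MIP reconstruction, intra-fraction motion, or tumour volume change,
and the plan model is spherically symmetric. Two consequences matter when
reading test results:

* A spherical dose core cannot conform to elongated PTVs the way a clinical
  VMAT optimizer does, so elongated-target ends sit in penumbra and the
  effective margin against motion is smaller than in clinic. Under the
  default conditions the delivered ITV minimum dose stays at or above the
  prescription in only about half the phantoms (it stays within ≈ 8% of the
  planned value), whereas clinical cohorts report ITV agreement within 1%.
  The deterministic part of the margin property — the ITV, being interior,
  can never be colder than the PTV — is what the test suite asserts.
* Pipeline-emergent distributions (DSC, ΔHI, per-lobe D95%) are *not*
  calibrated to the reference cohort's values; only the motion-amplitude
  ordering is. Quantitative recovery of the reference regression is tested
  on the separate tabular generator below, where the generating model is
  known exactly.

## Registration

`bspline_register()` is a documented stand-in for commercial multipass
B-spline registration; its fidelity criterion is known-truth recovery, not
agreement with any vendor. Per pass (control-point spacings 40/20/10 mm,
coarse to fine) it minimizes mean squared intensity error plus a Tikhonov
penalty on the pass's control coefficients (`lambda = 0.02`, on the mean
squared coefficient, which for B-splines is on the displacement scale) by
gradient descent: zero initialization, at most 50 iterations, the step
normalized so the largest coefficient update is `step_mm = 1` mm and halved
whenever the objective rises, stopping early at a relative improvement
below 1e−5. Each pass runs on an image pyramid level with voxel spacing
`max(native, cp_spacing / 2)` and is initialized from the accumulated field
of the previous passes; the moving image is always sampled at full
resolution through the current total map, so pyramid levels do not compound
interpolation blur. The optimizer is deterministic, so pipeline outputs
need no registration seed. On 6 mm-amplitude known-truth fields the mean
endpoint error inside the PTV is ≈ 0.2–0.5 mm, well under one voxel.

Supporting operations and their conventions:

* `invert_dvf()` — fixed-point iteration `v ← −u(y + v(y))`, with `u`
  extended by edge clamping so the iteration stays contractive at the grid
  border (with a zero extension, large boundary displacements make the
  iteration diverge); composition residuals on smooth non-folding fields
  are below 0.01 mm.
* `jacobian_log_stats()` — deformation gradient by central differences
  (one-sided at borders), determinant per voxel, summarized as the
  *natural* log: clinical registration-QA reports rarely state the log
  base, and ln is the registration-literature default, so it is pinned
  here. Quantiles use the linear-interpolation definition (R type 7),
  likewise pinned for reproducibility.
* `displacement_stats()` — the "Warp" statistics are computed over the
  PTV voxels only, following the convention that they summarize the
  displacement of the deformed target structure, and on the deformable
  part of the map: couch-corrected rigid motion is not "warp".
* Surface distances pool both directions (every surface voxel of A to the
  nearest of B and vice versa) and report mean/SD/max of the pooled set;
  surfaces are the mask minus its 6-connected erosion, distances are exact
  Euclidean between voxel centers. Clinical QA reports rarely state a
  direction/pooling convention for "surface distance"; the pooled
  symmetric variant is the common one and is used throughout.

## Dose evaluation choices

* The dose cloud is fixed to the plan isocenter in room coordinates; the
  residual setup error displaces the anatomy relative to it. An all-identity
  scenario therefore reproduces the plan *exactly* (the null-pipeline test
  asserts delivered ≡ planned to < 0.5 cGy with all QA metrics at their
  identity values — with identical images the MSE gradient is identically
  zero and the optimizer never moves).
* Dose warp-back uses the inverse of the *total* (rigid ∘ deformable) map,
  so "dose to tissue" is tracked per tissue element; commercial dose
  deformation does not document whether it inverts the forward map or
  registers in reverse, and the inverse-map choice is recorded here.
* Dose is interpolated as a point quantity; there is no Jacobian
  (mass/energy conservation) weighting. This matches standard
  dose-deformation practice and is a known limitation for strongly
  compressive fields.
* Per-fraction doses are rescaled ×4 to total-course units before
  averaging, so the accumulated grid compares directly with the planned
  dose.
* DVH points `Dx%` sort the masked voxel doses descending and interpolate
  linearly at rank `x/100 · N` (clamped to `[1, N]`); this removes DVH bin
  width as a hidden parameter and is validated against an exhaustive
  threshold-sweep oracle. V100%/V50% are absolute isodose volumes over the
  whole grid — clipping them to a structure would make GI and GM
  meaningless. Voxels count wholly in or out of masks; there is no
  partial-volume weighting, which deviates from TPS small-structure
  behaviour and slightly quantizes small volumes at 2.5 mm spacing.
* The gradient measure is reported in mm as the difference of
  equivalent-sphere radii of the 50% and 100% isodose volumes — the
  standard radii-difference definition (a dose-scaled variant sometimes
  seen in print is dimensionally inconsistent and is not used).

## The statistics layer

`generate_regression_table()` draws tabular case records from the reference
linear model for PTV D95% (intercept 2032.97; ΔHI −21.49; D_mean% 33.45;
DSC 558.55; Warp_mean −33.71, all in cGy per covariate unit), with
covariates independent by default: DSC ~ N(0.97, 0.06) truncated to (0, 1]
and Warp_mean ~ N(1.82, 1.09) truncated at 0 follow the reference cohort's
totals; ΔHI ~ Gamma(shape 2, scale 2.5) and D_mean% ~ N(100, 1.63) are
configuration defaults — no reference distributions are available for
these two covariates, coefficient recovery is distribution-agnostic, and
the D_mean% SD is back-solved from the reference model's
standardized-vs-unstandardized coefficient ratio. When `sigma_eps` is left `NULL` the residual SD is
calibrated as `Var(linear predictor) · (1 − R²)/R²` against the target
population R² (0.843), with the linear-predictor variance estimated from a
large fixed-substream Monte-Carlo draw. Independence keeps recovery tests
clean; a Gaussian-copula option (`copula_corr`) exists to induce the
collinearity (tolerance < 1, VIF > 1) seen in the clinical table.

`stepwise_mlr()` follows the SPSS stepwise convention:
entry at p ≤ 0.05, removal at p ≥ 0.10, iterated to a fixed point,
deterministic given the data; classical (non-robust) SEs and classical
one-way ANOVA, matching SPSS defaults. Standardized betas are
`B · SD(x)/SD(y)`; tolerance and VIF come from regressing each term on the
others, with `VIF · tolerance = 1` by construction. A worthwhile caveat
for any stepwise procedure at these thresholds: with two pure-noise
candidates the probability that neither enters is about 0.95² ≈ 0.90, so
"exactly the true terms selected" happens in roughly 85–90% of repeated
cohorts, not more — expectations above that rate are not achievable by the
procedure itself.

The subgroup refit excludes high-homogeneity-deviation cases. Whether the
threshold of 17 applies to the delivered HI itself or to its deviation
from the plan is a genuine ambiguity in such reports; the filter defaults
to ΔHI ≤ 17 (the quantity the regression uses) with the absolute-HI
interpretation selectable (`filter_subgroup(..., variable = "hi_del")`).
Outliers default to |studentized residual| > 3 — clinical reports often
designate outliers graphically without a numeric rule, so the 3-SD cut is
this package's documented choice. Fraction-level records are treated as independent
(no within-patient random effect), replicating the source analysis as-is.

## Problem sizes and budgets

Shipped analyses use the fast profile: 64³ voxels at 2.5 mm, 72 × 4
fractions (≈ 10 min end to end), 200-replicate regression recoveries
(seconds), 100-seed stepwise selection studies (seconds). Unit tests run on
32³–56³ grids. The fine profile (128³ at 1.25 mm) is available for
convergence checks but is not exercised by the shipped tests.

## Known limitations

Beyond the generator scope above: no OAR dosimetry; no DICOM-RT import
(volumes are NIfTI); no heterogeneity (HU-dependent) dose transport — the
analysis layer depends only on dose fields, not transport physics; the
spherical-core plan model under-represents clinical conformity for
elongated targets; and the DIR stand-in has no topology constraint beyond
its smoothness penalty (inversion and Jacobian QA would flag folding if it
occurred; at default amplitudes it does not).
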