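---
title: "Robust multi-isocenter VMAT total body irradiation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust multi-isocenter VMAT total body irradiation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbiplan)
```

## The problem

Total body irradiation (TBI) conditions patients for hematopoietic stem
cell transplantation by delivering a uniform prescription dose — typically
12 Gy or 13.2 Gy in eight fractions — to the whole body while limiting the
dose to lungs and kidneys. A modern alternative to the classic opposed
whole-body fields at extended distance is multi-isocenter
volumetric-modulated arc therapy (VMAT-TBI): the body is partitioned into
longitudinal *sub-targets*, each planned around its own isocenter, with
neighbouring dose distributions meeting at *junctions*. The price of the
technique is junction sensitivity: a longitudinal setup error between two
isocenters converts an abrupt field match into a hot or cold seam.

`tbiplan` implements the planning geometry of such a workflow end to end
at desk scale: synthetic whole-body phantoms with paired head-first (SHF)
and feet-first (SFF) scans, rigid pelvis registration and stitching,
rule-based PTV division, feathered AP/PA and step-wedge junction beams, an
idealized VMAT surrogate composite, the classic extended-distance AP/PA
comparator, SHF/SFF plan conversion, and setup-error robustness analysis.

## Coordinate and container conventions

All geometry lives in a patient frame with x lateral (patient left
positive), y anterior positive and z longitudinal (superior positive),
with the origin at a pelvis reference mark; distances are in mm
internally, while user-facing protocol parameters are in cm. Volumes are
regular rasters (`tbi_volume`); a feet-first scan stores its slices
reversed along z, which makes the "rotate series" step of plan conversion
an exact array transform rather than a bookkeeping convention.

## The synthetic phantom

The phantom is deliberately simple: an ellipsoidal head on a neck
cylinder, an elliptic-cylinder trunk and paired leg cylinders, with lung
and kidney ellipsoids embedded at configurable longitudinal positions.
Defaults scale with height using fixed anthropometric fractions (head
length capped at 24 cm, pelvis mark at 52% of height from the feet). The
rules the workflow implements only need correct topology, landmarks and
dimensions, so realism of shape is a non-goal. HU values are water (0 HU)
for soft tissue, −700 HU for lung and −1000 HU for air; bone is omitted
because the dose engine uses water-equivalent depth with a lung density
override only.

Soft tissue additionally carries a smooth, deterministic multi-scale
sinusoidal modulation (±100 HU, periods 5–13 cm, phases seeded). It
stands in for the internal anatomy that real pelvis CTs offer an intensity
metric. Without it the trunk is longitudinally uniform and *no* method
could localize a z shift in the pelvis overlap. Because the modulation is
smooth on the voxel scale, trilinear interpolation represents it
faithfully and the registration optimum stays unbiased.

Two-scan acquisition is emulated by cropping the whole-body volume into an
SHF scan (head to below the pelvis) and an SFF scan (feet to above the
pelvis) with a configurable overlap (default 10 cm, a value the protocol
does not pin down). The SFF scan of a displaced patient is *re-sampled
from the analytic model* at the displaced coordinates rather than
interpolated from the voxelized whole — a second acquisition of a moved
patient, not a smoothed copy — and the applied offset is returned as
registration ground truth.

## Registration and stitching

Registration is mono-modal CT-to-CT, so the metric is mean squared
intensity difference, minimized over translations (small rotations
optional, as setup differences in a vacuum bag are primarily
translational) by a coarse grid search plus Nelder-Mead refinement. Two
numerical choices matter:

* **Symmetric resampling.** Both scans are interpolated by half the
  candidate shift. Interpolating only the moving image attenuates its
  high-frequency content by an amount that depends on the fractional part
  of the shift, which biases the optimum toward grid-aligned shifts; with
  the symmetric form both images see identical smoothing for every
  candidate and the bias cancels.
* **Interior voxels.** The metric uses tissue voxels eroded 12 mm in from
  the body surface. A hard body–air edge reconstructed from samples
  carries its sampling phase, which a mean-squared metric happily aligns
  instead of the anatomy; the smooth interior intensities carry no such
  artifact.

With both choices, known offsets up to 10 mm are recovered to a few
hundredths of a millimetre on 5 mm grids. Stitching assembles the whole
body on the SHF grid with a hard transition at the mid-overlap plane (SHF
precedence above it) — deterministic and testable, where feathered
blending would be cosmetic.

## PTV construction and division

The PTV is the body contracted isotropically from the skin (default 3 mm,
configurable) minus lungs and kidneys. The published rule text gives the
contraction once as 5 mm and once as "3 mm in each direction"; the
parenthetical is the operational statement, so 3 mm is the default.

The division rules are driven by one derivation
(`compute_vmat_limit()`): plan quality constrains the superior–inferior
field width to the MLC travel limit (14.5 cm); split arcs double it to a
29 cm field; 5 mm margins per side leave a 28 cm optimization-target
limit; removing the 5 cm optimization feathering zone (OFZ, 2.5 cm per
interior end) leaves 23 cm per VMAT sub-target. The head sub-target runs
from the PTV top to the bottom of the neck (its optimization interval must
fit the 28 cm limit); 23 cm blocks stack inferiorly while the next full
block still ends at or above the top of the legs (the alternative — letting
the last block cross — is exposed as a flag); the remainder is covered by
equal-length AP/PA sub-targets of 25, 30 or 35 cm chosen to minimize the
isocenter count first and the length second, subject to covering the PTV
plus a ≥ 5 cm margin beyond the feet. The lookup is reconstructed from
those stated objectives — the original lookup table itself is not
published — and is verified against exhaustive search. Isocenters sit at
sub-target centres, junction points at junction-region centres, and all
points share the lateral/vertical coordinates of the pelvis-level PTV
centroid (rounded to 1 mm; the rule fixes that the coordinates are shared
but not how they are derived).

Pediatric cases shorten thoracic/abdominal sub-targets (never lengthen)
until one junction region lies inside the lung–kidney gap; a gap narrower
than the 5 cm junction is an error. Large patients shorten VMAT
sub-targets by 1–2 cm when the required lateral field exceeds a
threshold (default 40 cm), then re-tile.

## Dose model

The engine is primary-beam only: dose ∝ MU × segment weight ×
inverse-square from the source × a linear build-up ramp to `dmax` ×
exp(−μ_eff · WED), with water-equivalent depth (WED) accumulated along
the central-axis direction (parallel-ray approximation; exact cumulative
sums along axis-aligned beams, fixed-step sampling for oblique gantry
angles), lung voxels at relative density 0.3, and block transmission
exp(−μ_block · thickness). Defaults (μ_eff 0.049/cm at 6 MV, 0.044/cm at
10 MV, dmax 1.5/2.5 cm, 1 cGy/MU at dmax) are engineering values: the
contribution being tested is geometric and compositional, and a
transparent engine makes every junction property analytically checkable.
There is no scatter, penumbra or convolution model, deliberately.

Beam constructions follow the protocol: feathered AP/PA pairs (gantry
0°/180°, collimator 90°, 6 MV, three nested segments whose longitudinal
edges step in 2.5 cm decrements at junction-facing ends — the exact step
sizes are not published; 2.5 cm spans the 5 cm junction symmetrically and
yields a 3-level ramp), with the most inferior pair opened to the maximum
20 cm beyond the feet; nine step-wedge beams 40° apart (assumed to start
at 0°), five equal segments advancing in 1 cm steps to form the 5 cm
staircase; and the classic comparator (10 MV, 40 × 40 cm at 45° collimator,
SAD 400 cm — the collimator setting projects to 160 cm at the isocenter
plane, and the 45° rotation turns the square into a diamond that covers
the body length), with a 1 cm Lucite spoiler as added build-up, a
cerrobend lung block contracted 5 mm in beam's-eye view whose thickness is
solved in closed form for the 10 Gy (adult) or 8 Gy (pediatric) mid-lung
dose, a 4 cm kidney block, and MU normalized to deliver the prescription
at the maximum-thickness mid-separation point.

**The VMAT surrogate.** The inverse optimizer itself is out of scope; what
the workflow relies on is the distribution the step-wedge base dose
*forces* the optimizer toward: the prescription inside each optimization
interval, falling to zero across each junction as the complement of the
wedge. `compute_plan_dose()` therefore composes idealized per-isocenter
distributions with complementary *linear* ramps across every 5 cm
junction (a half-voxel rolloff at exterior ends). The linear ramp is the
idealization of the 5-level staircase: the staircase beams exist as real,
tested beam objects (fluence pattern, monotone wedge dose), and
`normalize_wedge_base()` ties their computed dose to the base the
surrogate complements, but the composite uses exact ramps so that junction
closure and the shift closed form below are analytic statements rather
than grid artifacts. AP/PA sub-targets can instead contribute engine dose
(`appa = "engine"`), which is what the delivery-equivalence checks use.

With complementary linear ramps of width w = 50 mm, a longitudinal error
δ of one isocenter perturbs the junction sum by exactly δ/w × rx — the
quantitative form of why feathering helps: an abrupt match line turns the
same δ into a ≈100% seam. Both statements are tested, the first as a
closed form on the surrogate composite, the second with engine-computed
feathered versus abrupt beams on a water block.

## Plan conversion and robustness

Delivery splits the whole-body plan at the pelvis origin point: beams with
superior isocenters deliver head-first; inferior ones are inverted to the
feet-first frame (collimator + 180°, gantry mirrored g → 360° − g,
isocenter x and z negated about the origin point) — an involution, chosen
so that with the engine's conventions the inverted beam on the rotated CT
reproduces the original dose exactly (verified to 10⁻⁶ Gy). An isocenter
exactly at the origin z is an error demanding a tie-break rather than a
silent assignment. Longitudinal table shifts between isocenters are
exported with each delivery plan and, per the image-guidance policy, are
locked during treatment: imaging corrects lateral and vertical errors only
(perfect correction by default, an optional residual fraction otherwise),
so the longitudinal component of a setup error always persists — which is
exactly what the junction closed form quantifies.

Setup errors are modeled as rigid dose-cloud shifts of per-isocenter
contributions, not dose recomputation through shifted anatomy: that
isolates the junction-matching mechanism under study and keeps the closed
forms exact. The scenario generator draws per-axis Gaussian shifts whose
region-dependent σ is calibrated so that P(any-axis |shift| > 5 mm)
matches clinically observed exceedance frequencies (head 38%, lung 62%,
abdomen 39%, pelvis 33%); this is a calibration of the generator, not a
reproduction of the clinical distributions, and is asserted only against
its own parameterization.

## Prescriptions, units, problem sizes

Both protocol regimens (150 and 165 cGy × 8) are supported via
`rx_fx`/`n_fractions`. Dose grids default to 5 mm isotropic; the phantom
default grid is 2.5 × 2.5 × 5 mm (5 mm slices). The test-suite and
worked examples voxelize phantoms at 5 or 10 mm isotropic — the division
rules depend on landmarks and extents, and every dosimetric assertion is
grid-consistent, so the coarser grids change nothing but runtime; those
sizes are the package's own choice of problem scale.

## What passing tests do and do not show

The phantom has correct topology, landmarks, organ placement and HU
classes, but no bone, no arms distinct from the trunk, no realistic CT
texture or noise. Registration accuracy on it demonstrates the metric and
optimizer are unbiased, not that real pelvis CTs register to 0.05 mm.
The engine validates geometry and composition laws (linearity,
inverse-square × attenuation, junction complementarity), not absolute
dosimetry; the clinical DVH population statistics of the source study are
not reproducible here and only directional statements (blocked lung mean
dose below open; surrogate PTV V100 above classic) are asserted.

## Known limitations

* The dose engine has no scatter or penumbra; junction behaviour near
  field edges is idealized by construction.
* The VMAT surrogate represents achieved distributions, not control-point
  sequences; MLC sequencing, arc optimization and treatment-console
  integration are out of scope.
* Block shadows use a parallel beam's-eye projection (divergence at
  SAD 400 cm across a ≤ 35 cm patient is below the dose-grid resolution).
* The rotation option in registration is exposed but the default phantom
  study exercises translations, matching the dominant clinical setup
  difference.
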