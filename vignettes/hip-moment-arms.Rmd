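---
title: "Corrected hip joint axes and tendon-excursion moment arms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corrected hip joint axes and tendon-excursion moment arms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiparm)
library(dplyr)
```

## The problem

Musculoskeletal models of archosaur hindlimbs (crocodilians, non-avian
dinosaurs, birds) are widely used to estimate muscle moment arms — the
effective lever of each muscle about a joint axis — across postures, because
moment arms connect reconstructed anatomy to locomotor function. A subtle
but consequential modelling error occurred in a family of published
comparative studies: as the femur was posed through a range of
flexion-extension angles, the hip's abduction-adduction and long-axis
rotation axes were left in their initial, pelvis-fixed orientations instead
of rotating with the femur. Flexion-extension moment arms were unaffected
(that axis genuinely is pelvis-fixed), but abduction-adduction and long-axis
rotation moment arms were computed about anatomically inappropriate axes at
every non-neutral posture.

`hiparm` implements the corrected axis convention as a reusable engine, and
deliberately retains the erroneous pelvis-fixed convention as a `legacy`
mode so the impact of the error can be quantified posture by posture.

## The joint model

The hip is a pure three-degree-of-freedom rotational joint between a static
pelvis and a mobile femur. The global frame coincides with the pelvis frame:
`x` craniocaudal, `y` proximodistal (the femur's long axis points along `-y`
at neutral), `z` mediolateral. Femur-local coordinates are expressed
relative to the joint centre at neutral, so posing the femur is a pure
rotation about the joint centre.

The rotation cascade is fixed, in the order FE → ABD → LAR:

1. **Flexion-extension (FE)** about the pelvis-fixed mediolateral axis `z`;
2. **abduction-adduction (ABD)** about the FE-rotated craniocaudal axis;
3. **long-axis rotation (LAR)** about the FE- and ABD-rotated proximodistal
   axis.

so the femur orientation is the intrinsic product
`R = R(z, fe) R(x', abd) R(y'', lar)`. This is the classic joint coordinate
system: the first axis is fixed to the parent segment, the last follows the
child, and the middle axis floats. The instantaneous axes follow three
rules, each of which is asserted by property tests over randomized postures:

* the FE axis never moves (`u_fe = z` at every posture);
* the ABD axis follows flexion-extension only
  (`u_abd = R(z, fe) x`), not abduction or long-axis rotation;
* the LAR axis follows flexion-extension and abduction
  (`u_lar = R(z, fe) R(x', abd) y`), not long-axis rotation itself.

In `legacy` mode all three axes stay at their neutral orientations
`(z, x, y)` forever — the published error. The two conventions coincide
exactly at neutral; for the FE degree of freedom at every posture; and for
the ABD degree of freedom whenever the flexion-extension angle is zero.
These coincidences are exact identities of the cascade and are tested at
`1e-10`.

Note that the corrected axis triad is *not* mutually orthogonal away from
neutral: `u_fe . u_lar = sin(abd)`. That is intrinsic to any
floating-axis joint coordinate system, not a defect; the orthonormality
requirements in the tests apply to each axis's unit norm, to the fixed pairs
(`u_fe ⊥ u_abd`, `u_abd ⊥ u_lar`) and to the femur orientation matrix.

### Sign conventions

Angles are in degrees throughout the interfaces (radians only internally).
The anatomical sign vocabulary follows the convention that **positive =
extension, adduction, lateral rotation** and **negative = flexion,
abduction, medial rotation**, for both angles and moment arms. Two
consequences deserve emphasis:

* the customary starting posture of *10 degrees of abduction* is
  `abd_deg = -10`;
* a muscle with a negative ABD moment arm is an abductor.

The mapping from anatomical angles to right-handed rotations about the
stored axis directions is carried by per-degree-of-freedom sense flags in
[hip_joint()], so a left-limb model is expressed by flipping the ABD and LAR
senses rather than by re-deriving conventions. Mirroring a model across the
`x`-`y` plane *and* flipping those two senses is exactly a limb-side swap
and preserves every anatomical moment arm — one of the package's property
tests. Mirroring the geometry alone negates ABD and LAR moment arms (and
preserves FE) at postures with zero abduction and long-axis rotation; at
other postures the mirrored model corresponds to the sign-negated posture,
so no posture-wise antisymmetry holds there, and the tests assert the exact
identities only.

## Moment arms

The moment arm of a muscle about a degree of freedom is defined by virtual
work: `r = -dL/dq`, the negative rate of change of muscle-tendon length with
the joint angle (in radians). A muscle that shortens as the angle grows has
a positive moment arm, so "positive = extensor / adductor / lateral
rotator" matches the angle vocabulary above.

Two implementations are provided and are kept deliberately independent:

* **Tendon excursion** ([excursion_moment_arm()]): the published studies'
  procedure. At each posture, the femur (and all femur-owned path points)
  is rotated by a half-step `h` forward and backward about the
  *instantaneous* axis of the tested degree of freedom — a pure hinge
  rotation through the joint centre, the other two angles held fixed — and
  the length difference is divided by the angle change (central
  differencing). The default half-step is `h = 0.25` degrees; the scheme is
  second order, so the truncation error falls fourfold when `h` is halved,
  which the tests verify.
* **Geometric** ([geometric_moment_arm()]): the exact derivative. For a
  path segment from a pelvis-owned point `a` to a femur-owned point `b`,
  a unit hinge rotation about axis `u` through centre `c` changes length at
  the rate `u . ((b - c) x e)`, with `e` the unit vector from `a` to `b`;
  summing over joint-crossing segments and negating gives the moment arm
  with no differencing at all. Segments wholly owned by one body are
  posture-invariant and contribute nothing.

The geometric method serves as the independent oracle for the excursion
method; the excursion method is retained because it is the procedure the
comparative studies actually used. On analytic hinge toys
([make_hinge_toy()]) with origin and insertion at distances `a` and `b` from
the centre, both must recover the closed form
`r(theta) = a b sin(theta) / sqrt(a^2 + b^2 + 2 a b cos(theta))`,
e.g. exactly `0.5` at `theta = 60` degrees with `a = b = 1`:

```{r toy}
toy <- make_hinge_toy(a = 1, b = 1, dof = "FE")
geometric_moment_arm(toy, "TOY", "FE", posture(60, 0, 0))
excursion_moment_arm(toy, "TOY", "FE", posture(60, 0, 0))
```

Muscle paths are ordered polylines of attachment and via points, each point
rigidly owned by the pelvis or the femur; wrapping surfaces are out of
scope. Degenerate geometry — a path segment collapsing to zero length at an
evaluated (or perturbed) posture — is an error, never silently skipped.

## The sweep protocol

[sweep_protocol()] encodes the published sampling scheme: the femur is held
at 10 degrees of abduction (`abd_deg = -10`) while flexion-extension is
varied in 15-degree increments. The flexion-extension range was not fixed by
the protocol (it differed across taxa); the default here is -90 to +90
degrees, i.e. 13 grid postures, and is configurable. [run_sweep()] emits one
record per muscle x dof x posture x mode, with moment arms both raw (model
length units) and normalized by femur length, the standard size correction
for cross-taxon comparison.

```{r sweep}
m <- make_hip_model(seed = 1)
rec <- run_sweep(m, sweep_protocol(modes = c("corrected", "legacy")))
glance(rec)
```

## Classification, group sums, cohort contrasts

[classify_function()] labels every muscle x degree of freedom from its
normalized moment arms over the grid: `obligatory-positive` /
`obligatory-negative` when the arm keeps one sign beyond a negligibility
threshold `epsilon` at every posture, `switching` when the sign changes
between adjacent grid postures (with the crossing angle linearly
interpolated between the bracketing pair — polarity switches with posture
are a genuine finding of the corrected analyses, e.g. a caudofemoralis that
abducts at flexed postures and adducts at extended ones), and `negligible`
when the magnitude never reaches `epsilon`. The default
`epsilon = 0.005` femur lengths makes "negligible" concrete where the
original studies said only "weak"; it is configurable, and labels are
scale-invariant by construction since they depend only on normalized
values. Profiles that hover on one side of zero without ever crossing
`-epsilon` (or `+epsilon`) are labelled with the side they act on.

[summarize_groups()] computes summed functional-group moment arms. Because
group membership is posture-dependent (muscles switch polarity), the sums
are formed by splitting each muscle's normalized arm by sign at each
posture: `summed_positive` adds the positive parts, and
`summed_negative_magnitude` adds the magnitudes of the negative parts, so
`summed_positive - summed_negative_magnitude` always equals the signed total
(a conservation identity the tests recount by brute force). Mean statistics
average the positive part and negative-part magnitude over all muscle x
posture cells with equal weights; no weighting scheme was published, so
equal weights are the least-structured choice.

[compare_cohorts()] contrasts cohorts (e.g. bipeds versus quadrupeds):
per-posture cohort means and standard deviations of the summed values, plus
cohort means of the per-model sweep means. [diff_modes()] quantifies the
legacy error itself: `corrected - legacy` per cell, with per-dof maxima and
the postures attaining them; its FE rows must vanish identically.

```{r classify}
classify_function(rec %>% filter(mode == "corrected")) %>% head()
glance(diff_modes(rec))
```

## The synthetic-model generator

No published taxon geometry is printed in the source material, so validation
rests on models built in code:

* **Hinge toys** with exact closed-form moment arms (above).
* **Randomized archosaur-hip-like models** ([make_hip_model()]) carrying
  the standard 19-muscle set (IF, CFB, CFL, PIFE1/2, PIFI1/2, ADD1/2, ISTR,
  ITBa/ITBp, FTE, FTI3, AMB, IFB, IFMa/IFMp, PIT). Attachments are drawn
  uniformly from anatomically flavoured regions: iliofemoral and
  iliotibial origins on the dorsal (and laterally biased) ilium,
  caudofemoral origins caudal to the hip (CFL furthest, reflecting its tail
  origin), adductor and puboischiofemoral origins on the medially biased
  ventral girdle, insertions on the proximal-to-mid femoral shaft, and a
  pelvis-owned via point for the PIFE muscles where they round the pubis.
  Coordinates are in femur lengths and rounded to six decimals, so a seed
  reproduces a byte-identical model file on any platform.

Two construction rules matter:

* **Conditioning**: candidate muscles are resampled until the
  joint-spanning path segment keeps a span of at least 0.4 femur lengths
  across the default sweep. A shorter span would put an attachment
  essentially on the joint capsule — implausible for these muscles — and
  the curvature of the length-angle curve grows like
  `rho^3 / span^2` (insertion radius `rho`), which degrades any
  finite-difference excursion estimate disproportionately.
* **Polarity targets**: an optional target forces a muscle's moment-arm
  sign for a degree of freedom. Targets are enforced by resampling until
  the normalized geometric arm keeps the required sign with a margin of
  0.01 femur lengths across the *whole default sweep grid*, not merely at
  neutral: "obligatory" is a sweep-wide property, and neutral-only
  enforcement cannot deliver it (many anatomies that satisfy a sign at
  neutral switch at extreme postures — exactly the phenomenon the corrected
  analyses report). Unsatisfiable targets (e.g. forcing the caudofemoralis
  longus to be an obligatory flexor) fail loudly, naming the muscle and
  degree of freedom.

What the generator does *not* emulate: real attachment footprints (points,
not areas), muscle wrapping over bone, knee-coupled two-joint geometry,
taxon-specific proportions, or any correlation structure between muscles.
Passing tests on these models therefore demonstrate the correctness of the
kinematics and the moment-arm machinery under the published protocol — they
do not reproduce, and cannot be compared to, the published per-taxon
curves, which require the original unpublished 3D geometries.

## Numerical choices

* Excursion half-step `h = 0.25` degrees by default (validity range
  `(0, 2]`); no scheme or step size was published, and central differencing
  at this step keeps the truncation error near `1e-5` femur lengths on
  well-conditioned geometry while staying far above floating-point noise.
* Rotation matrices are built by Rodrigues' formula; orthonormality and
  determinant are maintained at `1e-12` over the tested posture ranges
  without re-orthogonalization.
* Zero-length path segments are detected at `1e-12` femur lengths
  (tolerance, not exact equality, so a rotation landing a point on top of
  another within floating-point error is still caught).
* Classification treats an exact zero at a grid point as the crossing
  itself; zeros flanked by opposite signs interpolate to the zero's angle.
* Sweep output row order is fixed (model, muscle, dof, fe_deg, mode) so
  record tables are reproducible byte-for-byte.

## Problem sizes used in the validation suite

The bundled tests and the acceptance script size their simulations as: 100
seeded random models (19 muscles each) for the excursion-versus-geometric
oracle comparison over the 13-posture default grid, 3 degrees of freedom and
both axis conventions (~150,000 moment-arm evaluations); 1,000 randomized
postures for the axis-rule and orthonormality properties; 301 angles for the
hinge-toy closed form; and 10 models for the step-halving convergence ratio.

## Known limitations

* Two segments only (pelvis + femur); no knee or ankle chains, so two-joint
  muscles are represented only by their hip-crossing geometry.
* Via points are rigid; no wrapping surfaces or path solvers, so moment
  arms of muscles that wrap bone in reality are approximated by their
  polyline chord.
* No forces, activations or torques — moment arms only.
* The joint is purely rotational; no translations.
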