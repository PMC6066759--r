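---
title: "Digital fluoroscopy simulation for guide-wire insertion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital fluoroscopy simulation for guide-wire insertion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorotrack)
```

## The simulation model

`fluorotrack` models a radiation-free stand-in for intraoperative
fluoroscopy during dynamic hip screw (DHS) guide-wire insertion. The
physical system it abstracts is simple: a camera per radiographic plane
watches the operative field, two distinctly colored markers are fixed
to the guide-wire, and software overlays the tracked wire onto a
pre-loaded hip radiograph of that plane, producing a "simulated
radiograph" on demand instead of an X-ray exposure.

Three modelling assumptions define the scope:

* **Per-plane 2-D mapping.** Each plane (anterior-posterior, AP, and
  cross-table lateral, CTL) is treated independently as a planar scene.
  The camera-to-radiograph mapping is a 6-parameter affine transform
  fitted from exactly three user-selected point correspondences. No
  projective (8-DOF) model, lens-distortion model, or 3-D stereo
  reconstruction is attempted: within the roughly planar working
  volume of the wire, an affine map captures translation, rotation,
  anisotropic scale and shear, and three correspondences determine it
  exactly.
* **Rigid, straight wire.** The wire tip lies a fixed distance
  (`tip_offset`, a per-plane calibration input in pixels) beyond the
  distal marker along the proximal-to-distal marker axis. Wire bending
  is not modelled; the physical protocol the simulator supports
  explicitly instructs users not to bend the wire or cover the
  markers, and an occluded marker surfaces as a typed detection error
  rather than a guess.
* **Event-driven session.** A session is a small state machine:
  exposures, wire movements, and a single close event, each
  timestamped and logged. All five performance metrics are functions
  of this log plus the final wire pose.

## Marker tracking

Marker detection is an axis-aligned box threshold in RGB (`target` ±
`tol` per channel), followed by 8-connected component labelling; per
color, the largest component of at least `min_area` pixels (default
10) wins, and its intensity-unweighted centroid is the marker
position. Ties in area are broken toward the component whose top-left
pixel comes first in row-major order, or raise an error in strict
mode — every path is deterministic. A hue/saturation color model would
be more robust to illumination in the field, but is harder to reason
about in tests; the box model's noise behaviour is exactly
characterizable, and the tolerance is the single knob. With the
synthetic generator's disks (radius 4–10 px) the centroid is recovered
well within half a pixel under clipped Gaussian channel noise up to
σ = 8, which is the accuracy class the overlay needs.

The two markers are distinguished by *color*, not by geometric
ordering: role assignment survives partial occlusion and crossing
configurations that would confuse a sort-by-position rule.

## Geometry

`fit_affine()` solves the two 3×3 linear systems directly (one per
output coordinate). Three correspondences are exactly determining, so
least squares would add nothing but tolerance knobs; the direct solve
is bit-stable and its residual on the defining points is at machine
precision. Source triangles with twice-signed area below 10⁻⁶ px² are
rejected as collinear — sub-pixel clicks on any realistic frame never
legitimately approach this. Coordinates are 0-based with x = column,
y = row, origin at the top-left pixel corner, stated in every file
format the package writes. Because affine maps are not conformal, the
wire *direction* is mapped by transforming two points and
renormalizing, never by copying the camera-space direction.

## The five objective metrics

**Tip–apex distance.** The standard clinical definition: the sum over
both planes of the tip-to-apex distance corrected for radiographic
magnification. The primary correction uses the known true wire
diameter (`d_true_mm`, a config parameter — a typical DHS guide-wire
is 2.5 mm) against its apparent diameter in each plane's pixels, which
makes TAD invariant to uniformly rescaling either plane. When no
apparent diameter is measured the plane's `mm_per_px` scale is used
instead; both paths are tested. Whether the original hardware used the
diameter-based or a calibration-grid correction is not documented, so
both are provided and the choice is explicit in the API.

**Cut-out rate.** The literature's TAD-to-cut-out-risk relationship is
a steep monotone curve but its functional form is not printed anywhere
usable. The package models it as a two-parameter logistic on the logit
scale, `COR(t) = 100·logit⁻¹(a + b·t)`, pinned *exactly* through the
two extreme published cohort-median anchor pairs, (24 mm, 2.6 %) and
(47 mm, 55 %). This choice is validated internally: the calibrated
curve evaluates at the intermediate cohort's median TAD of 28 mm to
about 4.9 %, within half a percentage point of the published 4.7 %.
The curve is a plain two-field object, so an alternative calibration
can be substituted anywhere one is accepted. COR is reported to one
decimal place, matching the precision convention of the published
tables.

**Retries.** No published definition of a "retry" exists, so the
package defines one and documents it: hysteresis on signed insertion
depth, the projection of the tip onto the unit entry→apex axis of the
AP radiograph. The wire latches *inserted* above `depth_on = +5` px
and counts one retry when depth falls below `depth_off = 0` px
(unlatching). The 5-px band debounces tracking jitter at the cortex
while matching the intuitive meaning — a complete withdrawal followed
by re-insertion. Both thresholds are session parameters.

**Time and radiograph count.** Procedural time is wall-clock between
session open and the participant-declared close; in scripted replay it
comes from trajectory timestamps. Exposures are single per-plane shots
and the headline count sums both planes (a per-plane breakdown remains
recoverable from the event log, since the original reporting convention
for the total is unstated but one total is what is reported).

## Validity statistics

Cohorts are assigned from the DHS case count alone: novice < 10,
intermediate 10–39, expert ≥ 40. All comparisons are nonparametric.
The Kruskal–Wallis H uses midranks with the standard tie correction
and a χ²(k−1) reference; for total n ≤ 8 an exact permutation p is
also computed by enumerating every distinct assignment of the pooled
values to groups of the observed sizes. The Mann–Whitney U gives ties
half credit; its two-sided p is exact — all `choose(n, n_a)` labelings,
counting those at least as far from the null mean `n_a·n_b/2` as
observed — whenever total n ≤ 12, which covers every pairwise
comparison among cohorts of 8/7/11, and otherwise falls back to the
tie-corrected normal approximation with continuity correction. When
every pooled value is identical there is no evidence in either
direction, and H and U report 0 and p = 1 rather than NaN.

Post-hoc multiplicity uses the study family's fixed correction:
multiply each pairwise p by 3 and cap at 1. Percent differences
between cohort medians are `100·|m₁−m₂|/max(m₁,m₂)` rounded half-up
to an integer; the larger-denominator convention reproduces more of
the published pairwise table from the published medians than
smaller-denominator or mean-denominator alternatives. A handful of
published cells differ by one unit from any fixed rounding of the
rounded medians (they were presumably computed from unrounded ones);
the package reports what it computes and does not special-case them.
Likert agreement is the count and proportion of responses ≥ 5 on the
7-point scale.

## Synthetic data: what it does and does not emulate

The generators exist so that every stage is testable without hardware:

* `make_frame()` rasterizes two solid disks with center-of-pixel
  inclusion (a pixel belongs to the disk iff its center is within the
  radius) — this makes ground-truth pixel counts and centroids exactly
  computable — plus clipped Gaussian channel noise.
* `make_radiograph()` draws a schematic femur (bright head disk,
  neck/shaft band) and, crucially, carries *consistent annotations*:
  the apex on the head boundary along the neck axis and the
  lateral-cortex entry point.
* `make_trajectory()` / `make_insertion_trajectory()` script an
  attempt with a known number of withdraw/re-insert cycles and
  exposures, so replayed counters have exact expected values.
* `make_cohort()` draws TAD log-normally around each cohort's median
  target (right-skewed and positive, consistent with the non-normality
  that motivates the rank-based analysis), derives COR
  deterministically from TAD through the cut-out curve — the two
  metrics are functionally coupled, never independently sampled — and
  draws time (normal), radiograph and retry counts (Poisson) about
  their medians. Zero dispersion degenerates to every member sitting
  exactly on its cohort median.

Default cohort sizes (8/7/11) and all median targets are the published
study's values. The dispersion default (σ = 0.3 on the log scale) is
chosen for test power, since the real metric dispersions are
unpublished. Every generator is a pure function of its arguments and
seed: the global RNG stream is saved and restored around each call.

Passing tests on this synthetic data therefore demonstrates the
*pipeline's* correctness — geometry, detection, counters, statistics —
not photorealism: no DRR-style radiograph synthesis, no surgical
tremor model, no illumination or motion-blur effects on the frames,
and raw per-participant study data are unpublished, so the published
p-values themselves are not recomputable from any input. What can be
checked against the publication is checked: the percent-difference
table regenerated from the published medians, the cut-out curve's
consistency with the third printed anchor, and the qualitative
discrimination pattern on cohorts generated at the published medians
(at n = 50 per cohort the pipeline detects the novice/expert TAD and
COR separation in essentially every seed).

## Numerical choices

* Affine fit: direct linear solve; collinearity tolerance 10⁻⁶ px² on
  twice-signed area; inversion refuses |det| < 10⁻¹²; all geometry
  round-trips hold to 10⁻⁹ px in tests.
* Overlay rasterization: 2-px anti-aliased stroke with linear coverage
  falloff over half a pixel and *butt caps*, so the painted stroke
  terminates at the mapped tip to sub-pixel accuracy (a round cap
  would overhang the tip by up to width/2 + 0.5 px and bias any
  image-based tip readback). The 200-px drawn shaft length is purely
  cosmetic.
* Exact rank-test p-values compare statistics with a 10⁻⁹ slack when
  counting "at least as extreme" labelings, guarding against floating
  tie artifacts.
* Sessions are environment-backed objects: exposure/retry counters and
  the event log mutate in place, and a closed session refuses further
  mutation with a typed error.

## Problem sizes used in the test suite

The suite regenerates all fixtures in code: 100 random correspondence
sets for geometry round-trips; 100 noisy 120×160 frames for centroid
accuracy; exhaustive rank-test oracle comparisons over every 2- and
3-group composition with total n ≤ 8 (and all two-group splits for the
exact Mann–Whitney path); scripted sessions with 0–2 retry cycles and
7–26 exposures; and 100 seeds of 50-per-cohort synthetic cohorts for
the discrimination-rate property. These sizes give stable pass/fail
behaviour at comfortably sub-minute runtimes for each block.

## Known limitations

* The per-plane affine model ignores parallax between the wire's
  actual depth and the calibration plane; the companion hardware
  system may use richer stereo geometry, which is out of scope here.
* Marker detection has no temporal filtering; each frame is
  independent, so a single occluded frame raises rather than coasts.
* The retry definition, while defensible, is this package's own; a
  study logging retries by another rule would need the thresholds (or
  the event log) re-interpreted.
* The cut-out curve is an interpolation device calibrated to two
  anchor pairs, not a re-derivation of the underlying clinical
  regression; extrapolation far beyond 24–47 mm inherits the logistic
  form's assumptions.
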