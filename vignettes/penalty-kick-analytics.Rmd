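---
title: "Methods: pose-based penalty-kick strategy analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pose-based penalty-kick strategy analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penaltypose)
```

This vignette is the package's own account of its methods: what is being
modelled, which choices were open and how they were settled, what the
synthetic generator does and does not emulate, and what the numerical
behaviour is at the edges.

## The measurement model

A penalty kick is reduced to two annotated moments — the start of the
taker's run-up and the instant of ball contact — and two skeletons per
frame, each a fixed catalogue of 25 landmarks with image coordinates and
a confidence score. Three assumptions carry the whole geometric layer:

1. **The pitch is a plane**, so a single 3×3 homography `H` maps image
   pixels to field meters. `H` is estimated once per clip from ≥ 4
   corner correspondences by the direct linear transformation and is
   assumed constant over the clip (broadcast penalty framings hold the
   camera still between run-up and contact; a panning camera would need
   per-frame corners, which the data model accepts but the pipeline does
   not require).
2. **Left–right landmark pairs define orientation.** Both landmarks of a
   pair (shoulders, hips, toe pair of the support foot) are treated as
   lying at equal height, so their ground-plane projections preserve the
   pair's direction. The facing vector is `right − left` rotated +90°
   counter-clockwise; 0° faces the attacked goal, angles grow
   counter-clockwise (toward the kicker's left).
3. **Elevated single landmarks project with a height bias.** The
   neck and mid-hip used for the keeper's anticipation angle sit well
   above the ground, so their homography projections are displaced away
   from the camera — by meters, not centimeters. The anticipation angle
   is immune to the *shared* part of that displacement (it is
   translation-invariant) and uses the *directed* neck→mid-hip axis, so
   what it measures is the rotation of the torso's projected axis
   between the two moments.

### Why the directed axis, and why `[0°, 180°]`

The angle "between the two body lines" is ambiguous: undirected lines
fold the range to `[0°, 90°]`, making a keeper who reverses a lean
indistinguishable from one who holds still. The package uses directed
neck→mid-hip vectors, so a full reversal scores near 180° and holding
posture scores near 0°. This is the behaviourally meaningful ordering —
the quantity proxies how strongly the keeper commits — and it is the
convention all synthetic ground truth uses.

### Angle buckets and tie rules

The side Booleans use half-open buckets: right is `[0°, 90°) ∪
[270°, 360°)`, left is `[90°, 270°)`. The boundary angles are therefore
deterministic: 90° codes left, 270° codes right. Similarly, fitted
probabilities of exactly 0.5 in the logistic layer predict the positive
(dependent-strategy) class, and equidistant candidates in neighbour-frame
resolution resolve to the *earlier* frame — before ball contact the pose
is less occluded by the kicking action, so the earlier neighbour is the
safer substitute.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| confidence floor | 0.05 | score in [0, 1] | landmarks below this are treated as missing; the (0,0,0) sentinel alone misses near-zero garbage detections |
| neighbour window `max_offset` | 5 | frames | at 25 fps, ±0.2 s around the annotated moment; wider windows risk measuring a different phase of the movement |
| screening `alpha` | 0.05 | — | raw per-variable significance; no multiple-testing correction, mirroring the screening-then-model workflow this package reproduces |
| goal line `goal_line_x` | 0 | m | field frame origin is the center of the attacked goal line |
| logistic `maxit` | 50 | iterations | cap for IRLS under separation |

The confidence floor and window size were open choices (no published
values exist for either); both defaults are deliberately conservative and
every function exposes them.

## The statistical layer

Associations between coded variables and a dichotomized strategy use
Pearson's χ² without continuity correction; the effect size is Cramer's
V with classes weak (≤ 0.2), moderate (≤ 0.6), strong (> 0.6). Numeric
variables use the point-biserial correlation (identically Pearson on 0/1
coding, p from the t transform). Test-retest reliability is the Pearson
correlation of two measurement runs with the standard stability bands
(≥ 0.9 excellent, ≥ 0.8 good, …, exactly 0 none). Both band functions
are exact step functions; their boundary behaviour (≤ vs <) is unit
tested.

Strategy records coded *unclear* are retained in the data model but
excluded from the dichotomous analyses; the models treat strategy as
binary, and forcing a third level into them would change the estimand.

The logistic layer enters all retained predictors simultaneously (enter
method; no stepwise selection). Categorical predictors are dummy-coded
against their first canonical (alphabetical) level — the coding was not
an externally fixed choice, so determinism won. The model statistic is
the likelihood-ratio χ² `2(LL_full − LL_null)` on as many degrees of
freedom as estimated predictor terms. Published reports of this workflow
sometimes print df values near the sample size for these models; that is
not reproducible from the predictor counts, and the package reports the
standard likelihood-ratio df instead. In-sample accuracy at the 0.5
threshold is reported because that is what the workflow being reproduced
reports; it is an optimistic estimate, and with ~34 cases and a strong
single predictor the fit frequently separates — the package warns rather
than silently shrinking or stopping.

One arithmetic convention matters for reporting: the confidence summary
rounds half away from zero (with a one-ulp tolerance for binary
representation), because IEEE round-half-even turns a mean that is
exactly x.xx5 in decimal into the lower neighbour, which is not how
summary tables in this field are printed.

## The synthetic generator

`simulate_scene()` builds both skeletons **analytically in field
coordinates** and pushes them through the *inverse* camera map to
pixels, so ground truth is exact by construction: with zero pixel noise
the pipeline recovers every planted angle and displacement to ≤ 1e−6.
Its default geometry emulates the standardized behind-the-kicker
broadcast view at 1280×720: the camera homography is anchored to the
penalty-area corners, the kicker approaches from ~15.5 m out, the keeper
stands ~0.8 m off his line. The keeper's projected neck→mid-hip axis is
planted 4 m long, pointing behind the goal line when upright — the
length a ground-plane homography actually produces for a landmark ~1.5 m
above the pitch in this view. This matters for noise sensitivity: the
anticipation angle's robustness to pixel noise is governed by the
*image-plane* length of that axis (~50 px here), and a naively short
axis would make the measure look far noisier than broadcast geometry
warrants.

Noise is isotropic, landmark-independent Gaussian in pixels; confidence
scores are decorative draws from a clipped normal (mean 0.8, sd 0.14)
that do not perturb geometry. The generator does **not** emulate:
occlusion and detector dropout structure (missingness in real clips is
correlated with the kick phase), heavy-tailed detector errors,
person-swap identity failures, motion blur, or camera pan. Passing the
recovery tests therefore demonstrates that the *geometry and statistics*
are implemented correctly under the stated error model — not that the
upstream pose estimator is accurate on real broadcast video.

`simulate_ospaf_dataset()` plants a binary strategy at a set prevalence
and draws each coded variable from a strategy-conditional law; its
defaults are the study conditions this package targets: 34 penalties,
balanced strategies, the keeper's tactical action at population φ = 0.8,
run-up speed at φ = 0.35, a −50° anticipation shift (sd 10°) for
keeper-dependent records, and every other variable independent and
uniform. The planted φ values are returned in closed form
(`population_phi()`), giving association-recovery tests an exact target.

## Numerical choices

* **Hartley normalization is always on** in the DLT: pixel-scale
  coordinates produce constraint matrices with condition numbers around
  1e8 otherwise. The estimate is checked in the tests against an
  independent raw null-space solve (no normalization) to ≤ 1e−6
  relative on well-conditioned 4-point sets.
* A homography is stored normalized to `h9 = 1` when `|h9| > 1e−9`,
  else to unit Frobenius norm; rank deficiency of the DLT system
  (singular-value ratio < 1e−10) and singular matrices raise geometry
  errors rather than returning garbage.
* Projection errors at `|w′| < 1e−12` (points at infinity) raise rather
  than returning huge coordinates.
* Degenerate landmark pairs (separation ≤ 1e−6 m) and degenerate body
  axes raise typed errors; missing landmarks propagate as per-measure
  `NA` flags, never exceptions, so one occluded hip does not void the
  shoulder measure.
* Keypoint JSON is written with 17 significant digits so a
  write/read round trip is bit-exact.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
25 random 4-point sets for the homography cross-check, 200 one-penalty
scenes at 1 px noise for the anticipation-angle recovery, one simulated
coded dataset of n = 2000 for association recovery, and 20 replicates of
n = 200 for the null screening rate. These sizes put Monte-Carlo error
comfortably inside the tolerances being asserted while keeping a full
run in seconds.

## Known limitations

* One camera, one homography per clip; no lens-distortion or intrinsics
  model, no 3D reconstruction. Comparing penalties across different
  viewing angles needs a 3D treatment this package does not attempt.
* The equal-height assumption for left–right pairs is an approximation;
  a tilted shoulder girdle biases the projected orientation.
* Orientation of small pairs (the toe pair spans ~0.12 m) is noise-
  sensitive at broadcast resolution; the per-measure confidences exist
  precisely so downstream analyses can weight or filter.
* Classification accuracies are in-sample, as in the workflow being
  reproduced; no cross-validation is provided.
* Ball speed is an external numeric input; `ball_speed()` is a
  convenience displacement/time helper, not a tracking method.
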