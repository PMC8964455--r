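# penaltypose

Body-orientation and strategy analytics for football penalty kicks, from
2D pose-estimator keypoints and notational coding.

## The problem

In elite football, a penalty taker either pre-commits to a target
(keeper-independent strategy) or adapts the shot to the goalkeeper's
movement during the run-up (keeper-dependent); symmetrically, the keeper
either commits to a corner or reacts to the taker. Markerless pose
estimation makes it possible to quantify the body cues behind these
strategies directly from broadcast video: a pose estimator emits, per
person and frame, 25 skeleton landmarks as `(x, y, confidence)` triplets,
and two annotated moments — run-up start and ball contact — are enough to
derive the kinematic variables that matter.

`penaltypose` is for performance analysts and human-movement researchers
who have keypoint output, pitch-corner annotations and an observational
coding table, and want a reproducible path from those raw inputs to a
strategy-association analysis.

## What it computes

**Field registration.** The image-to-pitch map is a planar homography
`[x', y', 1]ᵀ = α H [x, y, w]ᵀ` estimated from ≥ 4 corner correspondences
by the direct linear transformation (SVD null-space solve with Hartley
point normalization). Field frame: origin at the center of the attacked
goal line, +x from the penalty spot toward the goal, +y to the kicker's
left.

**Body orientation.** For a left–right landmark pair (shoulders, hips, or
hallux / fifth toe of the support foot) projected onto the pitch, the
facing vector is `right − left` rotated +90° counter-clockwise; its angle
α is measured counter-clockwise from the goal direction, and the side
Boolean buckets it into right (`[0°, 90°) ∪ [270°, 360°)`) or left
(`[90°, 270°)`). Each measure carries the mean confidence of its pair.

**Goalkeeper anticipation.** αGK is the angle between the directed
neck → mid-hip body axes at run-up start and at ball contact (range
`[0°, 180°]`); foot displacements D_GKL / D_GKR are the Euclidean field
distances moved by the projected ankles between the two moments.

**Notational layer (OSPAF).** A validated 21-variable categorical coding
scheme for penalties (run-up speed/fluency/angle, kicking technique,
gaze, deception, keeper tactical action and performance, context, kick
placement, outcome, and the two strategy judgements). The package
validates levels, normalizes spellings, and joins codes with pose metrics
and ball speed into one per-penalty table.

**Statistics.** χ² association tests with Cramer's V
(`V = √(χ²/(N·(min(r,c)−1)))`, banded weak ≤ 0.2 < moderate ≤ 0.6 <
strong), point-biserial correlations for numeric variables, test-retest
reliability bands, and enter-method logistic regression with
likelihood-ratio χ² and in-sample classification accuracy — first on the
retained coded variables, then adding the retained pose variables to
measure the accuracy gain.

**Synthetic scenes.** A generator poses kicker and goalkeeper skeletons
analytically in field coordinates, pushes them through a broadcast-style
camera homography, adds Gaussian pixel noise, and emits the exact file
dialects the pipeline reads — so every stage is testable against known
ground truth without any video.

## Worked example

```r
library(penaltypose)

# a synthetic penalty: keeper anticipation 35 deg, 0.5 px keypoint noise
sc <- simulate_scene(scene_config(true_alpha_gk = 35, pixel_noise_sd = 0.5,
                                  seed = 8))
H <- estimate_homography(sc$corners)
extract_penalty_metrics(sc$kicker_track, sc$gk_track, H,
                        runup_start_frame = 0, ball_contact_frame = 9,
                        kicking_foot = "right")
#>   alpha_sh alpha_hi alpha_sf alpha_gk d_gkl d_gkr
#> 1    11.02    27.37    33.17    35.91  0.73  0.33
```

The anticipation angle (35.91°) and foot displacements (planted at 0.6
and 0.4 m) are recovered to within the noise; the orientation angles
scatter more because a shoulder pair spans only a dozen image pixels at
broadcast scale.

```r
# a coded dataset of 34 penalties with a planted keeper-strategy signal
sim <- simulate_ospaf_dataset(sim_study_config(seed = 8))
strategy_report(sim$features, "gk_strategy")
#> Strategy report: gk_strategy (positive = kicker_dependent), n = 34, alpha = 0.05
#>   retained after screening:
#>     gk_tactical_action       ospaf   stat =   14.435  p = 0.0001451  ES = 0.652
#>     location                 ospaf   stat =    6.606  p = 0.03677  ES = 0.441
#>     alpha_gk                 numeric stat =   -0.919  p = 1.765e-14  ES = 0.919
#>   OSPAF-only model:  logistic model: chi2(3) = 21.228, p = 9.442e-05, accuracy = 82.4%
#>   full model:        logistic model: chi2(4) = 47.134, p = 1.43e-09, accuracy = 100.0% [separation warning]
#>   accuracy gain from pose/numeric variables: +17.6%
```

Screening retains the planted keeper tactical action (strong effect,
V = 0.65) and the anticipation angle (r_pb = −0.92: lower anticipation
goes with keeper dependence); `location` is a chance retention at the 5%
screening level. Adding the pose variable lifts in-sample accuracy from
82.4% to 100% — with a separation warning, as expected at n = 34 when a
single variable nearly encodes the label.

A shell front-end wrapping the same functions ships in
`inst/cli/penaltypose` (`extract`, `analyze`, `simulate`, `validate`
subcommands).

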