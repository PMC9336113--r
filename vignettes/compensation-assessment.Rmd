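---
title: "Assessing compensatory motion from 2D video keypoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing compensatory motion from 2D video keypoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compens2d)
```

## The problem

After a stroke, patients recovering upper-extremity function often recruit
additional body segments to complete a reaching task: they lean the trunk
forward, rotate the torso, hike the shoulder, or tilt sideways. These
*compensatory motions* ease the task in the moment but can hinder true motor
recovery, so home-rehabilitation systems need to detect them and give
corrective feedback. `compens2d` implements a complete low-cost pipeline for
this: it consumes only 2D body keypoints (the 25-joint BODY_25 layout that
markerless pose estimators emit from an ordinary webcam), labels every video
frame with the compensation patterns it shows, and drives a virtual-coach
state machine that turns those labels into feedback events.

Four compensation categories are distinguished, encoded as labels 0-3, with
the exclusive label 4 for normal movement: Trunk Forward (TF, 0), Trunk
Rotation (TR, 1), Shoulder Elevation (SE, 2), and Other trunk patterns
(O, 3: trunk moving backward, trunk tilt). A frame may carry several labels
at once, so the problem is multilabel classification.

Three camera placements are supported: frontal (S1, used by exercises that
face the camera) and two side placements where the affected arm faces the
camera perpendicularly (S2) or obliquely (S3).

## From pixels to body frame

Raw keypoints arrive in image coordinates (pixels, y down) with a
per-joint detection confidence. Three cleansing rules run first:

* **Ghost removal** — spurious skeletons typically lack all three spine
  joints (Nose, Neck, MidHip at zero confidence); exactly those are removed.
* **Patient selection** — with several people in frame, the patient is the
  skeleton whose MidHip is closest to the image centre (ties break to the
  lower person index, for determinism).
* **Confidence filtering** — a frame is kept only if every *relevant* joint
  (affected-side shoulder/elbow/wrist, opposite shoulder, spine joints by
  default) has confidence strictly above 0.36 and every other joint above
  zero.

Kept frames are normalized in three steps: translate so the MidHip is the
origin (flipping y to up-positive, so "elevation" means increasing y);
divide by the baseline spine length (the Neck-MidHip distance at the first
kept frame) so body size and camera distance cancel; and — only for the
neural feature path — mirror the x axis so the affected limb always lies on
the positive side. The rule-based path never mirrors, because each of its
variables is already relative to a reference joint. The transformation is
translation-only by design: classifier outputs are then exactly invariant
to where the patient sits in the image and how far they are from the
camera, which the test suite asserts on randomly translated and rescaled
inputs. An optional rotation aligning the baseline spine with the vertical
is available but off by default, since a camera roll is rare and the
rotation would couple pixel noise into every variable.

Keypoint trajectories are filtered with a centred 5-frame moving average
(shrinking to the available samples at the edges, so constants are
preserved). Baseline ("t = 1") quantities are read off this filtered signal
at the first frame, where the shrinking window makes them the mean of the
first three frames: hanging the baseline on a single raw detection proved
to be the dominant noise source for baseline-referenced variables,
head area above all, since a convex hull over five noisy points has a
heavy-tailed area error.

## Kinematic variables and the rule-based classifier

Per scenario, the package computes per-frame variables chosen so that each
compensation category has a dedicated geometric signature:

| Scenario | Variable | Signature of |
|---|---|---|
| S1 | relative head-area change ΔH | trunk forward (+) / backward (−) |
| S1 | shoulder angles about the baseline neck, affected (1) and unaffected (2) | rotation (both rise), elevation ((1) alone) |
| S1 | trunk tilt angle | lateral lean |
| S2/S3 | spine angle and neck x displacement | sagittal lean |
| S2/S3 | shoulder x/y displacement relative to the neck | rotation (S2, x) and elevation (y) |
| S3 | absolute chest-length change | rotation seen obliquely |
| S2/S3 | absolute head-size change | lateral lean towards/away from camera |

Angles are reported in degrees (the arc cosine of a clamped normalized dot
product, vertex at the middle joint, so results lie in [0, 180]);
displacements are in body units (multiples of the baseline spine length);
ΔH is the relative change of the convex-hull area over the detected head
keypoints (Nose, eyes, ears by default; the shoelace formula on the hull).
The head model is pluggable because the pose layout has no head outline: if
fewer than three usable points remain, the squared inter-eye distance
stands in (it scales like an area); a collinear configuration with the
fallback disabled yields area 0 with a warning.

Two numerical choices deserve a note:

* **Spine angle vertex.** The spine/tilt angular displacement is computed
  at the MidHip — the body-frame origin, identical at baseline and current
  frame — between the baseline and current spine vectors. Placing the
  vertex at the baseline neck instead would make the formula undefined at
  its own baseline and near 90° for any infinitesimal neck motion, so no
  finite threshold could separate lean from noise; the MidHip vertex
  measures exactly the lean angle and is well conditioned.
* **Facing sign.** In side views, "forward" depends on which way the
  patient faces. X-displacement variables are oriented by a facing sign
  inferred from the nose-neck x offset at baseline, so positive always
  means "towards the facing direction".

The rule-based (RB) classifier applies independent per-frame threshold
rules to these variables and unions the results; an empty union is Normal.
In the frontal scenario the two shoulder angles interact: the affected
angle alone above `th_SE` reads as elevation; both above it read as
rotation; and when the affected angle additionally dominates by at least
`eps_gg` (15° by default) the frame gets rotation *and* elevation. The
printed rule distinguishes "difference ≈ 0" from "difference ≫ 0" without
quantifying either, so the package makes them concrete with `eps_eq` (5°)
and `eps_gg`, mapping the gap in between to rotation-dominant — the
decision is then continuous in the difference. One documented quirk follows
from this composite rule: raising `th_SE` is not monotone (it can
reclassify a rotation frame as elevation); every simple one-variable rule
is monotone in its threshold, and the test suite pins down exactly these
properties.

Default thresholds (all configurable, per scenario) are calibrated on the
synthetic benchmark geometry: S1 uses ΔH 0.20, shoulder/tilt angles 10°;
side views use 5° of spine lean, 0.10 body units for shoulder
displacements and chest-length change, and 0.20 for head-size change. They
sit roughly an order of magnitude above the smoothed noise floor at
realistic pixel jitter while keeping a 2× compensation comfortably inside
the detected range. A trunk-priority option that suppresses shoulder
elevation whenever a trunk label fires in the same frame is available but
off by default — it mirrors a known failure mode where a trunk tilt is
misread as shoulder elevation, at the cost of deviating from the rule set
as published.

## The two-stage neural classifier

Normal frames vastly outnumber compensation frames, so a single multilabel
network tends to collapse to "Normal". The neural path therefore splits the
problem: a binary gate C1 (ReLU activations) decides whether *any*
compensation is present; a one-vs-rest multilabel stage C2 (tanh
activations), trained only on compensation frames, decides *which*. Frames
gated negative are Normal and never reach C2; gated-positive frames take
every label whose C2 score clears 0.5, falling back to the single
highest-scoring label so no gated-positive frame is left unlabelled.

Features are the mirrored, spine-normalized (x, y) coordinates of a fixed
13-joint subset (spine, both shoulders and hips, affected elbow and wrist,
eyes and ears), side-resolved so a left-affected and a right-affected
subject in mirror-symmetric poses produce identical rows; confidences are
never features. Both stages are small multilayer perceptrons trained with
Adam (Glorot-uniform initialisation, mini-batches of 5, at most 550
epochs, L2 penalty 1e-4, early stopping when the epoch loss stops
improving by 1e-4 for 10 consecutive epochs), implemented in the package
because the exact activation/optimiser combination is part of the method.
Training is deterministic given a seed. Per-exercise architecture defaults
are 1×16 (gate) with 1×64 (identifier) at learning rate 0.001 for E1, 2×16
and 1×16 (0.001/0.01) for E2, and 1×96 (0.01) with 1×16 (0.001) for E3; a
grid-search routine over the wider architecture/rate space exists but is
never run by default. Class imbalance is deliberately left unhandled in
training (beyond the two-stage split itself), matching the method as
described; a class-weighting switch would be the first thing to add for
real data.

## Evaluation

Multilabel performance is summarised micro-averaged: true/false positives
and false negatives are pooled over every (frame, label) slot before
computing precision, recall and F1, and Hamming loss is the fraction of
mispredicted slots. The Normal label participates as a fifth slot so that
all-Normal predictions are scored; this is the main comparability caveat
when reading the numbers against published tables whose counter definition
is not spelt out. Zero-denominator precision/recall return 0 with a
warning. Dataset structure is described by `p_min` (the single-label
fraction) and per-label imbalance ratios `IRLbl` (modal label = 1; labels
that never occur are NA).

Cross-validation is leave-one-subject-out (one fold per subject, held-out
subject never in training, fold metrics averaged unweighted with their
standard deviation) and leave-one-exercise-out for the two frontal
exercises, which share the positioning scenario — training on one exercise
and testing on the other, in both directions.

## The synthetic generator

Real patient recordings of this kind cannot be shared, so the package
ships a generator that emulates the statistical structure the classifiers
rely on, and doubles as the test oracle. It is a 2D articulated stick
model posed directly in the image plane per scenario — not a 3D renderer,
which is sufficient because every classifier input is 2D keypoints. A
seated pose with a reach-and-return arm movement spans each trial;
scripted episodes then deform the geometry so that the kinematic variable
each rule watches takes exactly `magnitude × threshold` at the episode
plateau, with linear 5-frame on/off ramps: head-area scaling for trunk
forward/backward, opposed shoulder rotations about the neck (frontal) or a
shoulder x shift / chest-length change (side views) for rotation, a
shoulder raise for elevation, and a spine rotation or head scaling for
tilt. During side-view leans the affected shoulder also gets a small
(±0.5 `th_TR`) offset along the facing direction, emulating scapular
protraction/retraction — without it the printed forward/backward sign rule
would have nothing to read, since a rigid lean leaves the shoulder-neck
offset unchanged. Isotropic Gaussian pixel noise (σ = 2 px in the noisy
benchmark), a constant confidence level of 0.9 and an optional
misdetection probability are applied last.

Ground truth is *rule-consistent*: the generator records the analytic
noise-free value of every rule variable it injects, smooths those series
with the same 5-frame window the pipeline uses, and thresholds them with
the matched thresholds. Episodes must start at frame 4 or later so the
three baseline frames are at rest. On noise-free data the full pipeline —
keypoints, cleansing, normalization, kinematics, rules — reproduces the
injected variables to floating-point precision, so recovery is exact by
construction *through an independent code path*; that equality is what the
noiseless acceptance check verifies. Defining truth as "frames overlapping
an episode" instead would mislabel ramp frames whose injected effect is
still below threshold.

Datasets draw subject templates from realistic ranges (spine 170-230 px,
shoulder half-width 0.30-0.40 spine, random affected side, side views
split between S2 and S3 for the cane exercise), with 0-2 episodes per
trial and configurable kind weights; a rare-label configuration reproduces
the strongly imbalanced regime where one label's imbalance ratio dwarfs
the others. Contamination utilities add ghost skeletons, an off-centre
second person and sub-0.36 confidence dropouts, and cleansing provably
restores the clean kept-frame set.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: true post-stroke kinematic signatures
(spasticity, segmented reaching, tremor), occlusion-driven correlated
keypoint errors, rolling-shutter or lighting artifacts, annotator
disagreement in the labels, and compensation magnitudes that hover near
threshold rather than sitting at a scripted multiple of it. Results on the
benchmark are a verification of the machinery, not a clinical validation.

## The virtual coach

The coach is a reflex agent over eight states: out-of-position, in
position, exercise, normal movement, trunk rotation, shoulder elevation,
trunk displacement, and target-reached. Eleven transition rules map state
changes to feedback events (speech tags with a subtitle table — no audio
synthesis — plus coloured markers for the placement rectangle, the hand
target, and shoulder/trunk compensation indicators). Where the published
description names but does not quantify its parameters, the package
chooses and documents: repositioning prompts repeat after `th_pos` = 5 s
out of position; encouragement comes after `th_tg` = 10 s of evaluation
without reaching the target; the target counts as reached when the
affected wrist is within 0.15 body units of the target point; movement
onset is wrist speed above threshold for 3 consecutive frames and a stop
is 15 frames below it. Labels 0 and 3 both map to the trunk-displacement
state; when several labels fire in one frame the state priority is trunk
rotation > shoulder elevation > trunk displacement (configurable).
Returns to the normal-movement state are silent, the target state is
absorbing until an explicit new-trial signal (which re-enters the exercise
state and re-shows the target marker), and offline replay substitutes
frame-count time for the wall clock, making the event log a pure function
of the observations and configuration.

## Problem sizes and limitations

The validation suite works at desk scale, chosen so the whole suite runs
comfortably on one CPU: the recovery benchmarks use 6 subjects × 10 trials
× 75 frames (25 fps, i.e. 3 s per trial), metric equivalence uses 1000
random 500-frame prediction pairs, and the cross-validation harnesses run
on the same benchmark. Known limitations: thresholds are global, not
per-patient; the head-area variable remains the noisiest signal even after
filtering; the S1 composite shoulder rule is non-monotone in `th_SE` as
printed; velocity, smoothness and range-of-motion measures are out of
scope; and the neural path, like any learned model, inherits the
generator's geometry when trained on synthetic data.

```{r, eval = FALSE}
# A minimal end-to-end run
tpl <- subject_template("S1", "right", noise_sd = 2)
script <- compensation_script(75, list(
  list(kind = "se", start = 20, end = 45, magnitude = 2)))
trial <- generate_sequence(tpl, script, seed = 1)
pred <- rb_assess(trial$sequence)
mlc_metrics(trial$labels, pred)
```
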