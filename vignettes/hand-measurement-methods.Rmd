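---
title: "Hand measurement from tracked skeletons: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hand measurement from tracked skeletons: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handmetrics)
```

## The measurement model

`handmetrics` treats a tracked hand as a rooted tree of coordinate frames:
the wrist at the root and, per finger, the chain metacarpal → proximal →
intermediate → distal → tip. Every edge carries the child frame expressed
in its parent as a rigid homogeneous transform (rotation block plus a
translation in millimetres), so any transform between two hand frames is
the composition along the unique tree path. All measures are read off
these matrices:

* sizes are norms or components of edge translations,
* joint angles are `atan2` expressions of the z-column of a relative
  rotation (the z-axis of each bone frame points along its bone),
* ranges of motion are extrema of per-sample angles over a motion trace.

This mirrors how frame graphs are used in robot middleware, but the graph
here is in-process: there is no transform broadcasting, no device driver,
and the trace file (a documented JSON-lines dialect, schema in
`inst/extdata/trace-schema.json`) is the only input.

### Frame placement and the off-by-one that comes with it

Tracking APIs report each bone by its begin and end point. We place each
bone's frame at its *begin* point (the tip frame at the fingertip), which
makes the translation of the edge *into* a frame span the *preceding*
segment: the edge into `index_proximal` measures the index metacarpal. The
low-level `bone_length()` is deliberately literal about this — it returns
the edge norm of the frame you name — while `segment_length()` and
`finger_length()` speak anatomically and do the index shift internally.
The edge from the wrist into a metacarpal frame is the carpal offset and is
never counted as a bone.

### Conventions fixed by this package

Several conventions the underlying measures need are not fixed by the
measurement model itself; we fix them once and document them here:

* **Euler angles**: intrinsic x-y-z (`R = Rx(roll) Ry(pitch) Rz(yaw)`),
  with roll the rotation about x — the wrist roll used for the range of
  motion. At gimbal lock (|pitch| = 90°) roll and yaw are inseparable;
  the result carries a flag, yaw is set to 0 and roll absorbs the
  remainder, so reconstruction still reproduces the rotation.
* **Quaternions**: scalar-first `(w, x, y, z)`. Tracking devices emit
  slightly denormalised quaternions, so norms within 1e-6 of 1 are
  silently renormalised; anything worse (and any zero quaternion) is an
  error.
* **Wrist roll parent frame**: the roll angle is extracted from the
  wrist-in-sensor pose carried on each sample. Whether the tracked wrist
  pose is expressed relative to the sensor or the forearm is a property of
  the acquisition setup, not of the trace format; the measure is a span
  (max − min), so a constant parent offset cancels.
* **Sides**: spread angles of left hands are mirrored about x before
  extraction, so positive spread points toward the index side on either
  hand; flexion, a rotation about x, is unaffected by the mirror.
* **Hand-length ties** resolve to the first finger in the fixed order
  index, middle, ring, pinky.
* **Printed vs anatomical finger length**: the hand-length formula's bone
  list omits the intermediate phalanx. The default `finger_length()` sums
  all four bones (anatomically complete); `mode = "printed"` reproduces
  the three-bone list exactly. Both are ground-truthed by the generator.
* **Wrist range sign**: the defining difference (min − max) is
  non-positive; the range is reported as its magnitude.
* **Dropouts**: samples missing a frame a measure needs are skipped and
  counted; a measure fails once more than 50% (configurable) of samples
  were unusable.

## The haptic procedure and its simulated wrist

The haptic session ramps a force perpendicular to the wrist–effector lever
(1 N/s by default, 1 ms control step) until the deflection crosses the
threshold angle (default 15°), then holds the force until the angle varies
by less than 0.1° over 0.5 s, keeps it there for a 2 s hold, and saves
(angle, force, direction). The force never exceeds the 12 N device cap —
sessions that would need more terminate `force-capped` at exactly the cap —
and the per-step angular update is clamped so the effector never exceeds
the speed limit (100 mm/s default). Ramp rate, control step, hold time,
stability window and speed limit are not dictated by the procedure itself;
the defaults above were chosen once to be slow and safe, and every one is
configuration. Deflection angles support both full 3-D vectors and the
planar (x-y) mode; planar is the default, matching a constrained-axis
measurement where out-of-plane motion is suppressed. The forearm-holder
tilt (3.5°) is carried as session metadata: it documents the physical
setup and enters no computation.

The wrist the controller pushes against is a **synthetic stand-in**: a
torsional spring in force-to-angle form (angle = force/stiffness, so a
"gain" of 2 deg/N is a stiffness of 0.5 N/deg) with an optional
first-order damping lag and a flexion/extension gain asymmetry. Zero
damping — the default — makes linear plants quasi-static, which is what
makes the analytic check possible: the held force must equal
threshold/gain to within one ramp increment. The plant makes no
biomechanical claims; identification of real wrist stiffness or damping is
out of scope.

## What the synthetic generator emulates — and what it does not

`generate_trace()` forward-kinematically poses a hand with rigid,
specified bone lengths, smooth scripted joint trajectories (sinusoidal
wrist roll; raised-cosine flexion and spread ramps), and a seeded noise
model: Gaussian position noise applied to joint points *before* frame
construction (so the begin/end redundancy in the file dialect stays
self-consistent) and small random rotations composed onto bone frames.
Default dimensions are plausible adult anthropometry (middle-finger chain
64 + 45 + 27 + 18 = 154 mm, hand width ≈ 64 mm at the proximal frames);
the thumb metacarpal has zero length, as the tracked model reports it.
Scripted amplitudes are validated against anatomical bounds (|roll| ≤ 90°,
flexion ≤ 110°, spread ≤ 40°).

The ground-truth record is computed from closed-form expressions evaluated
at the trace's sample times — a code path sharing nothing with the
transform-graph measures — and reports each range both as the analytic
extremum of the continuous waveform and as the extremum attainable at the
sampled instants (the two differ by at most one sampling step's angle
increment). One deliberate subtlety: when spread and flexion run
simultaneously, the metacarpophalangeal flexion angle as the z-column
formula sees it acquires a `cos(spread)` crosstalk term; the ground truth
reproduces that closed form rather than the scripted amplitude, so
recovery tests remain exact under combined motion.

What the generator does **not** emulate: soft-tissue artefacts, tracking
dropouts and occlusion (dropouts can be injected but are not part of the
noise model), correlated or pose-dependent sensor error, tendon coupling
between joints, and pathological motion patterns (contracture, spasticity).
Passing recovery tests therefore shows the *computational pipeline* is
exact and noise-consistent — not that a particular sensor achieves any
given accuracy on real hands.

## Agreement statistics

Sessions follow the repeated-measures design of device-comparison studies:
5 participants × 15 repetitions per hand part per device by default. The
repeatability SD is defined as the mean over participants of
per-participant sample SDs (denominator n − 1). The defining equation
admits a second reading — one pooled SD over all values centred on their
participant means — which is available as `method = "pooled"`; the default
follows the per-participant reading because it matches the stated intent
of summarising repeatability across participants. The difference of means
pairs participants before averaging (`mean |x̄_A,p − x̄_B,p|`) rather than
differencing grand means, which would let between-participant differences
cancel. Pearson correlation is computed on pooled per-repetition pairs
within a measure family (lengths; angles), via `stats::cor()` behind a
contract that rejects fewer than 3 pairs or zero variance. Left and right
hands pool by default; sides can be analysed separately by filtering the
result table.

## Numerical choices

* Rigid-transform validation demands orthonormality and determinant +1
  within 1e-9, and an exact `(0, 0, 0, 1)` last row; inverses use the
  closed rigid form rather than a general solve.
* Angles are computed in radians internally and reported in degrees; all
  `acos` arguments are clamped to [−1, 1].
* Rotation-to-quaternion extraction uses Shepperd's branch selection and
  canonicalises to w ≥ 0 (quaternions are defined up to sign).
* Trace serialization is canonical — fixed field order, full
  floating-point precision — so equal traces are byte-identical, seeded
  generation is reproducible to the byte, and write–read–write is
  byte-stable. Each sample carries its raw serialization record so a
  rewrite does not re-derive (and so never perturbs) the stored numbers.
* Zero-length bones are legal: their frames keep their given orientation.

## Problem sizes used by the tests and acceptance script

The shipped tests generate traces of 4 s at 60 fps (241 frames) for
recovery checks, a hundred to a thousand random instances for the geometry
and telescoping oracles, haptic sessions at the default 1 ms control step,
and 5 × 15 synthetic session batches for the statistics — sizes at which
every check runs in seconds while still exercising the asymptotic
behaviour (dense sampling relative to the scripted waveforms, multiple
noise levels). `scripts/acceptance.R` re-runs the same computations from
scratch with a caller-supplied seed.

## Known limitations

* Thumb-specific measures (opposition, circumduction) are not defined.
* The spread measure assigns fixed per-finger shares of the scripted total
  spread; real hands spread non-uniformly, which affects the per-finger
  angles but not the telescoped total.
* The haptic plant is first-order; oscillatory or hysteretic wrist
  behaviour can only be approximated (sessions that never stabilise are
  reported `unstable` rather than mis-measured).
* Grip-force measurement and wrist stiffness/damping identification are
  out of scope.
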