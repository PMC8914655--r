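# handmetrics

Hand diagnostics after stroke needs quick, repeatable measurements of hand
geometry and joint mobility, but the standard tools — goniometer, caliper,
dynamometer — measure one joint at a time by hand. `handmetrics` implements
the computational core of an automated alternative: it turns skeletal
tracking data (the per-bone positions and orientation quaternions a sensor
such as the Leap Motion exposes) into clinically meaningful hand measures,
and simulates the haptic force-ramp procedure by which a robotic effector
measures wrist range and the force needed to deflect the wrist.

The package is for rehabilitation engineers and movement scientists who
want to compute, test or extend these measures without any device attached:
a synthetic hand generator with analytic ground truth stands in for the
sensor, and a configurable torsional-spring wrist stands in for the
patient.

## What it computes

The hand is modelled as a rooted tree of coordinate frames (wrist →
metacarpal → proximal → intermediate → distal → tip per finger), each edge
a rigid homogeneous transform `H` with rotation block `R` and translation
`t` in mm. From this graph:

* **bone length** `L = ||t||₂` of the edge spanning the bone;
* **hand length** `HL = max over fingers {I, M, R, P} of (L_m + L_p + L_i + L_d)`
  (the thumb is excluded; the metacarpal is included because the tracked
  model folds carpal length into it; a printed-equation mode omits the
  intermediate phalanx);
* **hand width** `HW = |x|` of the translation between the pinky- and
  index-proximal frames;
* **wrist range** `WM = |min RA − max RA|` where `RA` is the wrist roll
  angle (rotation about x) collected over a motion trace;
* **finger spread** `FSR = Σᵢ (θᵢ₊₁ − θᵢ)` over fingers numbered pinky (1)
  to index (4), with `θ = atan2(z_x, z_z)` of the metacarpal→proximal
  z-column — a sum that telescopes to `θ_index − θ_pinky`;
* **finger flexion** `FF = max(angle_MP) + max(angle_TIP)`, with each angle
  the `atan2(z_y, z_z)` of the corresponding relative transform.

The haptic module ramps a force perpendicular to the wrist–effector lever
until the deflection angle (sum of the angles between the entry vector A
and the extreme vectors B and C) crosses a threshold (default 15°), holds
it until the angle stabilises, and records (angle, force, direction) —
honouring a 12 N force cap and an effector speed limit throughout.

Device agreement is summarised the way measurement-comparison studies do:
pooled repeatability SD (mean over participants of per-participant sample
SDs), difference of means `DM = (1/Nₚ) Σₚ |x̄_A,p − x̄_B,p|`, and Pearson
correlation per measure family.

## Worked example

```r
library(handmetrics)

spec   <- hand_spec()                      # default adult hand, right side
script <- motion_script(roll_amplitude_deg = 45, spread_amplitude_deg = 28,
                        mp_amplitude_deg = 55, pip_amplitude_deg = 42,
                        dip_amplitude_deg = 18)
gen <- generate_trace(spec, script, noise_model(), seed = 17)
gen$trace
#> <motion_trace> 241 frames | right hand | 4.00 s @ 60 fps

hand_length(gen$trace$samples[[1]]$graph)
#> $length_mm
#> [1] 154
#> $finger
#> [1] "middle"

wrist_motion_range(gen$trace)$wm_deg     # scripted 45 deg roll -> 90 deg span
#> [1] 90
finger_spread(gen$trace)$fsr_deg
#> [1] 28

res <- run_haptic_measurement(wrist_plant(stiffness_n_per_deg = 0.5),
                              haptic_config())   # gain 2 deg/N, 15 deg target
res
#> <haptic_result> flexion | angle 15.00 deg | force 7.500 N | completed
```

The measured hand length is the middle-finger chain of the default spec
(64 + 45 + 27 + 18 = 154 mm); the 45° roll script spans ±45°, hence a 90°
wrist range; and a linear wrist of gain 2 deg/N needs 15/2 = 7.5 N to reach
the 15° threshold — which the simulated controller finds to within one ramp
increment.

A command-line wrapper covers the same workflow from a shell:

```sh
exec/handmetrics simulate --out trace.jsonl --seed 7
exec/handmetrics measure  --trace trace.jsonl --out results.csv
exec/handmetrics haptic   --out haptic.csv
exec/handmetrics compare  --a results_a.csv --b results_b.csv --out report.csv
```

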