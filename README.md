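# scapsim

A self-contained R toolkit for simulating the human shoulder with an
articulated scapula. Most upper-extremity models couple scapular motion to
humeral elevation through a fixed "scapulohumeral rhythm", which makes it
impossible to simulate shrugging or to ask how much mechanical work the
thoracoscapular muscles (trapezius, serratus anterior, rhomboids, levator
scapulae) actually do. `scapsim` models the scapulothoracic articulation as
a true 4-degree-of-freedom joint — the scapula glides on a thoracic
ellipsoid with coordinates for abduction, elevation, upward rotation and
winging — and drives it with muscles, so scapular and humeral motion are
independent and muscle work can be attributed honestly.

The package is aimed at movement scientists and biomechanists who want a
scriptable, dependency-light environment for shoulder kinematics, muscle
moment arms, muscle-driven tracking simulation, and work/EMG analysis.

## What is inside

* **Model core** — a built-in shoulder model with 33 Hill-type
  (rigid-tendon) musculotendon actuators spanning thorax, clavicle,
  scapula, humerus and forearm, plus readers/writers for TRC marker files,
  MOT/STO motion files, and a documented XML model subset. The muscle
  architecture (maximum isometric force, optimal fiber length, tendon slack
  length, pennation) is from the published aggregation of the Klein
  Breteler / van der Helm bundle set; the attachment geometry is an
  authored approximation shipped for download-free testing, not anatomical
  ground truth.
* **Scapulothoracic kinematics** — the ellipsoid joint
  (`scapula_transform()`), whole-model forward kinematics, damped
  least-squares marker inverse kinematics (`solve_inverse_kinematics()`),
  and calibration of ellipsoid tilt/radii (`fit_thorax_ellipsoid()`).
* **Muscle geometry** — path lengths with sphere/cylinder/ellipsoid
  wrapping, tendon-excursion moment arms `r = -∂L/∂q`, operating-range
  checks, and the incremental +2 % optimal-fiber-length / matched
  tendon-slack-reduction tuning loop (`tune_muscle_lengths()`).
* **Muscle mechanics** — rigid-tendon Hill model
  `F = (a·f_L(l̃)·f_V(ṽ) + f_P(l̃))·F_max·cos α` and first-order
  activation dynamics (τ_act = 10 ms, τ_deact = 40 ms).
* **Tracking control** — a static-optimization variant of computed muscle
  control: PD desired accelerations
  `q̈* = q̈_des + k_v(q̇_des − q̇) + k_p(q_des − q)`, per-step redundancy
  resolution `min Σa² + w_r Σ(r/r_scale)²` with heavily penalized reserve
  actuators, forward integration of the muscle-driven skeleton
  (`run_tracking()`).
* **Analysis** — muscle power `P = F_mtu·(−v_mtu)`, positive work over the
  elevation phase, external work as the change in gravitational potential
  energy, thoracoscapular vs glenohumeral work grouping
  (`work_summary()`), and mean-absolute-error comparison of activations to
  EMG envelopes with serratus-bundle averaging (`activation_mae()`).
* **EMG** — the standard conditioning chain: zero-phase 4th-order
  Butterworth high-pass at 100 Hz, full-wave rectification, zero-phase
  low-pass at 4 Hz, then MVC normalization (`emg_envelope()`,
  `normalize_mvc()`).
* **Synthetic data** — minimum-jerk joint-angle trajectories for shrug,
  flexion and abduction (with/without a 2 kg hand mass), 120 Hz marker
  trajectories with Gaussian noise, and amplitude-modulated band-limited
  EMG-like signals, all seeded and reproducible (`task_spec()`,
  `generate_task_kinematics()`, `generate_marker_data()`,
  `generate_synthetic_emg()`).

A thin command-line wrapper over these functions is installed at
`inst/cli/scapsim` (subcommands `fixtures`, `ik`, `moment-arms`, `track`,
`emg`, `work`).

## Worked example

Generate a loaded-abduction trial, solve inverse kinematics from noisy
markers, run the muscle-driven tracking simulation, and summarize work:

```r
library(scapsim)

model <- builtin_thoracoscapular_model(hand_mass = 2)
spec  <- task_spec("abduction", hand_mass = 2, marker_noise_sd = 0.003,
                   seed = 42)
qt    <- generate_task_kinematics(spec, model, fs = 120)
trc   <- generate_marker_data(model, qt, noise_sd = 0.003, fs = 120,
                              seed = spec$seed)

ik <- solve_inverse_kinematics(model, trc)
round(ik$rmse_total * 100, 2)   # marker RMSE, cm
#> [1] 0.46

tuned <- tune_muscle_lengths(model, as.matrix(qt[seq(1, nrow(qt), 24), -1]))
res   <- run_tracking(tuned$model, qt, t_end = 2.3)  # elevation phase
ws    <- work_summary(tuned$model, res, task = "abduction")

round(c(total = ws$total, external = ws$external), 1)
#>    total external
#>     53.9     26.2
head(ws$per_muscle[order(-ws$per_muscle$positive_work_J), 1:3], 3)
#>                     muscle           group positive_work_J
#> 13       Deltoideus.Middle    glenohumeral       13.135788
#> 29  Supraspinatus.Anterior    glenohumeral        8.204722
#> 2  Trapezius.ScapulaMiddle thoracoscapular        8.114564
```

The marker RMSE (0.46 cm here) is the fit of the model to the noisy
synthetic markers. The work summary shows total positive muscle work
exceeding the external (potential-energy) work — lengthening muscles absorb
energy that other muscles must supply — and, on the abduction tasks, the
thoracoscapular trapezius + serratus anterior group out-working the
deltoids. Numbers depend on the authored fixture geometry; with an
anatomical model file (`read_model()`) the same pipeline applies.

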