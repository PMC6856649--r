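---
title: "Methods: the scapsim thoracoscapular shoulder model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the scapsim thoracoscapular shoulder model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Why a scapulothoracic joint

Most shoulder models couple scapular motion to humeral elevation with a
fixed regression ("scapulohumeral rhythm"), which makes shrugging and
independent scapular motion impossible and lets glenohumeral muscles do
work that thoracoscapular muscles (trapezius, serratus anterior, rhomboids,
levator scapulae) actually perform. scapsim instead models the scapula
gliding on a thoracic ellipsoid through a 4-degree-of-freedom joint, with
the thoracoscapular muscles driving it, so that questions about who does
the mechanical work of elevating the shoulder girdle can be asked of the
model directly.

## The scapulothoracic joint

The joint is parameterized by the ellipsoid semi-axes $(r_x, r_y, r_z)$ and
four coordinates:

* **abduction** $a$ and **elevation** $e$ are surface angles placing the
  contact point through the trigonometric parameterization
  $p = (r_x \sin a \cos e,\; r_y \sin e,\; r_z \cos a \cos e)$, which lies
  on the surface identically;
* **upward rotation** $u$ rotates the scapula about the outward surface
  normal at the contact point;
* **winging** $w$ rotates it about the surface tangent along the elevation
  direction (the medial border), lifting the border off the thorax.

The scapula frame origin *is* the contact point, so for $w = 0$ the
implicit surface equation is satisfied by construction. Because $a$ and
$e$ are surface angles, their effective lever is the ellipsoid radius: one
radian of elevation translates the scapula by roughly $r_y \approx 0.21$ m
in the fixture. Interpreting task amplitudes has to respect that metric
(see *Synthetic tasks* below).

The clavicle is connected at the sternoclavicular point by a zero-DOF
"aim" joint that keeps it pointed at the scapula's acromial facet. This is
a kinematic strut, not an articulated clavicle: it adds no coordinates,
but it carries clavicular muscle attachments (anterior deltoid, clavicular
trapezius and pectoralis major) along with the shoulder girdle, which
keeps their operating ranges physiological. The glenohumeral joint is a
ball (elevation-plane convention: plane angle about the vertical axis,
elevation about the rotated horizontal axis, then axial rotation); the
forearm and hand are lumped on an elbow hinge, and a hand-held mass can be
welded to the hand point.

## The built-in fixture model

`builtin_thoracoscapular_model()` carries the published 33-actuator
architecture (maximum isometric force, optimal fiber length, tendon slack
length, pennation) exactly. Everything else — attachment coordinates, wrap
geometry, segment masses and inertias, marker placements — is *authored*:
chosen so each muscle's line of action produces qualitatively correct
moment signs (superior trapezius elevates and upward-rotates the scapula,
serratus anterior protracts and upward-rotates, deltoids elevate the
humerus, and so on) on a 1.62 m / 52 kg frame with de-Leva-style segment
mass fractions. It is a testing fixture, not anatomical ground truth:
absolute work values and activation magnitudes from it should be read as
model-scale results, while sign structure, inequalities and rankings are
the quantities the test-suite asserts. Anatomically curated geometry can
be supplied through `read_model()`.

Moment arms follow the tendon-excursion definition $r = -\partial L /
\partial q$ (central difference, default step $10^{-5}$ rad). Sphere and
cylinder wraps are tangent-arc-tangent closed forms; the ellipsoid wrap is
solved numerically as the shortest polyline that does not penetrate the
quadric: red–black Gauss–Seidel relaxation of interior points toward
neighbour midpoints with orthogonal projection (Newton on the Lagrange
multiplier) back to the surface, coarse-to-fine from 9 to 33 points by
default (cold accuracy about $10^{-5}$ m; call `wrap_over_surface()` with
`n_points = 257` for $10^{-6}$ m work). Inside sweeps and tracking loops,
solves are warm-started from the previous pose with a fixed short
relaxation, which keeps the length a smooth, deterministic function of
pose — important because moment arms are finite differences of it. A
segment that merely grazes a surface takes the straight (zero-arc limit)
branch, keeping lengths continuous; an attachment *inside* a wrap surface
raises the undefined-path error, naming muscle and surface.

## Muscle mechanics

A rigid-tendon Hill-type model: fiber length
$l_f = (l_{MTU} - l_{ts}) / \cos\alpha$ with constant pennation $\alpha$,
and tendon force
$F = \left[a\, f_L(\tilde l)\, f_V(\tilde v) + f_P(\tilde l)\right] F_{max}
\cos\alpha$. The rigid tendon is appropriate here because several
actuators have zero or near-zero tendon slack length. Curve shapes
(`hill_curves()`, all configurable):

* active force–length: Gaussian $\exp(-(\tilde l - 1)^2 / 0.45)$, shifted
  and rescaled to be exactly 0 at $\tilde l = 0$ and 1 at the optimum — the
  shift makes force continuous across the slack transition, which the raw
  Gaussian (value 0.108 at zero fiber length) violates;
* passive: $\left(e^{4 (\tilde l - 1)/e_0} - 1\right)/(e^4 - 1)$ above
  optimal length, zero below, with the strain-at-$F_{max}$ constant
  $e_0 = 1.0$ — softer than a single-muscle curve because each actuator
  aggregates several anatomical bundles whose staggered passive engagement
  softens the lumped response;
* force–velocity: Hill hyperbola on the shortening side (shape factor
  0.25, $v_{max} = 10\, l_{opt}$/s), $C^1$-continuous eccentric branch
  with plateau 1.4.

Activation follows a first-order lag toward excitation with
$\tau_{act} = 10$ ms and $\tau_{deact} = 40$ ms, advanced by the exact
exponential update and clamped to $[0, 1]$.

When a motion drives fibers outside the 50–150 % operating range,
`tune_muscle_lengths()` applies the incremental remedy: optimal fiber
length increased by 2 % per step with tendon slack length reduced by the
same absolute amount, until the muscle is back in range or the slack
length would go negative (clamped at zero and stopped, logged). This is
part of preparing the model for a motion; the built-in model always
returns the printed parameter table untouched.

## Inverse kinematics and ellipsoid calibration

`solve_inverse_kinematics()` minimizes the weighted marker error per frame
by damped least squares (Levenberg–Marquardt with a monotone objective,
tolerance $10^{-10}$ on the objective decrease), warm-starting each frame
from the last. Three safeguards address the arm-hanging degeneracy, where
the humeral elevation plane is momentarily unobservable (at zero
elevation, plane and axial rotation act identically). First, a small
Tikhonov prior (weight $10^{-4}$) anchored at the *previous frame's*
solution: along flat directions of the marker objective the minimum then
stays where the last frame left it, giving temporal coherence by
construction. Second, a rescue: a frame fitting much worse than its
recent neighbours (or worse than 8 mm outright) is re-solved from the
default pose and from the current solution reflected about the defaults —
the reflection maps the mirrored ball-joint branch (plane $\pm 180°$ with
elevation negated), which fits identically while the arm hangs but runs
into the coordinate clamps once it elevates, back onto the true branch;
an alternative is adopted only on decisive (factor-two) improvement so
equal-fit branches never alternate. Third, each frame is polished with
the prior re-anchored at its own solution (weight $10^{-5}$), which
removes the temporal-prior bias on well-observed coordinates — the
reported fit is exact on noise-free data — while still pinning sloppy
directions against per-frame noise chasing. Frames with fewer than three
visible markers are flagged and interpolated.

`fit_thorax_ellipsoid()` calibrates the joint: Nelder–Mead over
log-radii and three tilt angles, with the full IK marker error of a
calibration trial as the objective; the best-seen parameters are kept, so
the post-fit objective never exceeds the pre-fit one.

## Tracking controller

`run_tracking()` is a per-step static-optimization variant of computed
muscle control. At each control step (10 ms) it computes the PD desired
acceleration $\ddot q^* = \ddot q_{des} + k_v(\dot q_{des} - \dot q) +
k_p(q_{des} - q)$ with $k_p = 100$ s$^{-2}$, $k_v = 20$ s$^{-1}$
(critically damped), linearizes each muscle's force in activation at the
current kinematics, and solves

$$\min_{0 \le a \le 1} \; \sum_i a_i^2 + w_r \sum_j (r_j / r_{scale})^2,
\qquad R\,(a \circ F_{act} + F_{pas}) + g + r = M \ddot q^* + c$$

with $w_r = 1000$, $r_{scale} = 1$ N·m, reserves eliminated analytically
and the box-constrained quadratic solved by projected quasi-Newton
iterations with an analytic gradient, warm-started. The excitation
command deadbeat-inverts the activation lag (landing activation on the
target at the step end, clamped to $[0,1]$), and the initial activations
are the static-equilibrium solution so no artificial start-up transient
appears in the reserve log.

The skeleton is integrated at 1 ms substeps with the muscle geometry
(moment arms, lengths, mass matrix, Coriolis forces) frozen over the
control step and gravity and the PD law refreshed every substep; the
reserve torque at each substep is the exact residual enforcing the
commanded acceleration — penalized at the optimization stage, logged
honestly, and never a free actuator. Dynamics terms come from
central-difference body Jacobians (mass matrix), the potential-energy
gradient (gravity) and the Christoffel contraction of the mass-matrix
gradient (Coriolis), so the work–energy bookkeeping closes: muscle work
plus reserve work equals the change in kinetic plus potential energy up
to integration error (the test suite requires 2 %). A small armature
inertia ($10^{-4}$ kg·m$^2$) regularizes poses where a coordinate is
momentarily inertialess (the elevation plane with the arm hanging).

Reserve share is reported per coordinate as RMS reserve torque over RMS
net muscle torque (`reserve_share()`). With the authored fixture geometry
the share stays below 5 % on the scapular coordinates during shrugging and
on the humeral elevation coordinate during the arm tasks, and reserve
*work* stays below 10 % of muscle work on every task; the tests assert
exactly that. On the scapular coordinates during high arm elevation the
share is larger: the glenohumeral muscles' forces react on the scapula,
and the approximate thoracoscapular attachment geometry cannot always
balance those reaction torques muscle-only — a geometry-fidelity
limitation of the fixture (see Known limitations), not of the controller.
On coordinates whose net muscle torque is essentially zero (axial humeral
rotation during a shrug) the ratio is meaningless and only the absolute
reserve torque is informative.

## EMG processing

The conditioning chain is a zero-phase (forward–backward) 4th-order
Butterworth high-pass at 100 Hz, full-wave rectification, and a zero-phase
4th-order Butterworth low-pass at 4 Hz, with residual ringing clamped at
zero; envelopes are normalized by the maximum of the processed envelope
across MVC trials. The 4th-order design is chosen so the chain's passband
droop at 150 Hz stays within a few percent of the ideal mean-rectified
value $2A/\pi$ of a sinusoid; a 2nd-order design applied twice loses about
17 % there. Raw EMG sampling must exceed 200 Hz for the high-pass corner
to be meaningful; the synthetic generator uses 1000 Hz (hardware rates are
not dictated by the 120 Hz kinematic capture).

## Work accounting

Muscle power is $P = F_{MTU} \cdot (-v_{MTU})$ with $v_{MTU}$ positive
when lengthening, so concentric contractions yield positive power;
positive work is the trapezoidal integral of $\max(P, 0)$ over the
elevation phase, detected as the span from 5 % of the primary
coordinate's excursion to its peak (scapular elevation for shrug, humeral
elevation otherwise). External work is the change in system potential
energy (all segments plus any hand-held mass) between the phase
endpoints, hence path-independent. Per-muscle work is grouped into
thoracoscapular (trapezius, serratus anterior, rhomboids, levator
scapulae, pectoralis minor) and glenohumeral (deltoids, rotator cuff,
teres major, plus latissimus dorsi, pectoralis major, coracobrachialis,
biceps and triceps, which cross the joint anatomically); muscles below
3 % of the total are flagged as excluded from headline rankings. Because
lengthening muscles do negative work and segments accelerate relative to
the centre of mass, total positive muscle work exceeds external work on
every elevation task — an inequality the test suite asserts on all six
fixture tasks.

## Synthetic tasks

The generator reproduces the study battery: three trials each of shrug,
forward flexion and abduction, with and without a 2 kg hand-held mass
(18 trials), as minimum-jerk elevation-and-return profiles over 4 s,
markers at 120 Hz with 3 mm isotropic Gaussian noise, and EMG-like
signals (band-limited 20–450 Hz carriers at 1000 Hz, amplitude-modulated
by activation, signal-to-noise 10). Seeds derive from (task, load, trial),
so the battery is reproducible trial by trial.

Two amplitude choices deserve their rationale:

* **Shrug peak, 12°.** Because scapular elevation is a surface angle, its
  lever is $r_y = 0.21$ m: 12° raises the scapula about 4.4 cm, the upper
  range of a vigorous shrug. (30° would translate the scapula ~11 cm,
  slacken the anterior deltoid entirely and demand elevator torques no
  muscle set can supply — an amplitude that parameterization cannot
  express physiologically.)
* **Arm-task peak, 110° of humerothoracic elevation**, split 2:1 between
  the glenohumeral coordinate (73.3°) and scapular upward rotation
  (36.7°) — the classic scapulohumeral rhythm expressed as an emergent
  *target* for the tracking controller, not a model constraint. Applying
  the full 110° at the glenohumeral joint *and* half of it again as
  upward rotation would stack to ~165° of arm elevation and shred the
  muscle operating ranges.

What the generator does not emulate: soft-tissue artifact on markers,
electromechanical delay or crosstalk in EMG, inter-trial human
variability (trials differ only by noise seed), and anatomical geometry
beyond the authored fixture. Passing tests therefore demonstrate the
correctness of the algorithms and the internal consistency of the
pipeline, not subject-level predictive accuracy.

## Problem sizes and numerical choices

The test suite and the acceptance script run the six-task battery at one
trial per condition, 120 Hz inverse kinematics over the full 4 s
trajectories, and muscle-driven tracking over the elevation phase
(about 2.3 s) at the default 10 ms / 1 ms control and integration steps.
The ellipsoid calibration test recovers perturbed radii from a short
noise-free calibration trial at reduced frame rate. Tolerances asserted in
the tests: $10^{-6}$ m for closed-form wrap oracles, $10^{-5}$ m for
moment-arm oracles, 2 mm per 0.5° for moment-arm continuity, $10^{-6}$
for the activation-dynamics exponential, 5 % for the EMG chain against the
mean-rectified closed form, 2 % for the work–energy balance, and 1 cm for
marker RMSE of inverse kinematics on noisy data.

## Known limitations

* Attachment geometry is authored, not measured; absolute forces, works
  and activation levels are fixture-scale. At high arm elevation the
  thoracoscapular muscle set cannot fully balance the scapulothoracic
  reaction torques of the large glenohumeral muscle forces, so scapular
  reserve shares rise there; with measured anatomical geometry (an
  imported model file) the same controller would lean on reserves less.
* The clavicle strut has no axial rotation and the scapulothoracic contact
  is bilateral (the joint can pull as well as push); winging is restrained
  only by muscles.
* Rigid tendon everywhere; no glenohumeral stability or joint-reaction
  analysis.
* The tracking controller has no look-ahead window; reserves absorb
  whatever the linearized muscle set cannot produce within a step, and are
  reported rather than hidden.
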