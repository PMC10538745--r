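---
title: "Simulating osseointegrated transfemoral amputee gait with osseogait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating osseointegrated transfemoral amputee gait with osseogait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osseogait)
```

## The problem

After a transfemoral amputation with an osseointegrated (bone-anchored)
prosthesis, the femur is transected, a titanium implant is fixed inside the
residual bone, and a prosthetic knee-ankle-foot replaces the lost limb.
Understanding how the remaining muscles and the prosthesis share the work of
walking requires a musculoskeletal model: a digital skeleton with inertial
properties, a roster of Hill-type musculotendon units, and idealized torque
actuators at the prosthetic joints, driven through the standard motion
analysis workflow — scaling, inverse kinematics (IK), inverse dynamics (ID),
residual reduction, static optimization, and a tracking forward simulation.

`osseogait` implements that entire workflow as a self-contained,
sagittal-plane R package. It builds a generic healthy lower-extremity model
(23 degrees of freedom, 92 musculotendon units) and transforms it into the
amputee model (19 DOF, 76 units, two ideal actuators), reads and writes the
TRC/MOT/STO motion-capture formats, and ships a synthetic gait-trial
generator so every stage can be exercised and tested without access to
motion-capture hardware.

## The models

The healthy skeleton follows the structure of the classic 23-DOF gait model:
a pelvis floating relative to the ground (6 DOF), a lumped torso on a
3-DOF lumbar joint, ball-and-socket hips (3 DOF each), revolute knees and
ankles, and two foot coordinates (subtalar, metatarsophalangeal) per side
that are typically locked. The 92 musculotendon units are symmetric: 43 per
leg plus 3 lumbar-support units per side.

`apply_amputation()` performs the unilateral transform with the generic
prosthesis constants: the femur transected to 0.247 m (mass 4.65 kg, with
inertial properties recomputed for a bone density of 350 kg/m^3), a
0.205 m / 0.35 kg implant welded to the residual femur, a 0.43 m / 1.4 kg
tibia pylon carrying the prosthetic knee and ankle revolutes (joint centres
mirroring the contralateral side), and a 0.8 kg prosthetic foot. Sixteen
muscles lost with the limb (vasti, gastrocnemii, soleus, deep plantarflexors,
tibialis anterior and the other dorsiflexors, peronei, biceps femoris short
head) are removed; eight bi-articular muscles (semimembranosus,
semitendinosus, biceps femoris long head, sartorius, adductor magnus, tensor
fasciae latae, gracilis, rectus femoris) are re-attached to the residual
femur — losing their knee moment arm — and disabled. Counting note: the
adductor magnus is represented by three musculotendon units, so the eight
anchored *muscles* correspond to ten anchored *units*; the unit total is
92 − 16 = 76 either way.

```{r counts}
healthy <- build_healthy_model()
amputee <- apply_amputation(healthy)
c(dof_healthy = dof_count(healthy), mtu_healthy = mtu_count(healthy),
  dof_amputee = dof_count(amputee), mtu_amputee = mtu_count(amputee))
amputation_summary(amputee)
```

## Sagittal-plane scope

The dynamic engine is planar. Ten coordinates carry dynamics: pelvis
fore-aft and vertical translation, pelvis tilt, lumbar extension, and
hip/knee/ankle flexion per side. The remaining coordinates of the full
roster (pelvis list/rotation/tz, lumbar bending/rotation, hip
adduction/rotation, the locked foot joints) are kinematic placeholders held
at neutral: a planar marker model cannot observe them, and the synthetic
trials never excite them. Sign conventions: x forward, y up; hip flexion,
knee flexion, ankle dorsiflexion, and anterior pelvic tilt are positive.
Gait cycles run 0–100% from heel strike.

Dynamics use a world-frame recursive Newton-Euler pass; the mass matrix is
assembled column-by-column from unit-acceleration inverse dynamics, which
keeps forward and inverse dynamics mutually consistent to machine precision
(the test suite checks the ID-of-FD identity at 1e-6 relative tolerance and
the pendulum period against its closed form to 0.1%). Welded chains — the
residual femur and its implant — are collapsed into composite rigid bodies
by mass summation, barycentric centre of mass, and the parallel-axis
theorem. Integration is semi-implicit Euler.

## Muscle model

Each unit is a rigid-tendon Hill muscle: force
`F0 * (a * fl(l) * fv(v) + fp(l))`, linear in the activation `a` at fixed
fiber kinematics — the linearity every per-frame optimizer exploits. The
curve shapes are package defaults: a Gaussian active force-length bell of
width 0.45, the classic Hill hyperbola on the concentric side with an
eccentric plateau of 1.4, and an exponential passive toe region that reaches
the maximum isometric force at 60% strain. Activation follows a first-order
lag with 10 ms rise and 40 ms fall time constants, advanced by an exact
exponential update.

Musculotendon kinematics come from constant sagittal moment arms packaged
per muscle (out-of-sagittal-action muscles carry zero arms but remain in
every roster and cost term). Two related choices matter:

* **Operating point.** Fiber length is anchored so that every muscle sits at
  its optimal length in a mid-gait posture (hip 15°, knee 25°, ankle −5°)
  rather than at the neutral pose. In full musculotendon models this job is
  done by tendon-slack-length tuning; without it, rigid-tendon extensors are
  force-length-starved at flexed postures and gait-level torque demands
  become infeasible.
* **Rigid tendon.** Fiber velocity equals musculotendon velocity, which
  overstates the force-velocity penalty at push-off relative to an
  elastic-tendon model. The default study conditions (below) were chosen so
  that gait demands stay within this conservative capacity.

## The analysis pipeline

**Scaling** measures marker-pair distances on a static trial (pelvis width,
thigh, shank, foot, trunk) against the model's virtual markers, applies
per-segment factors to geometry, inertia (factor squared) and muscle
lengths, optionally rescales masses to a subject total, and reports the
static marker RMSE against the ~1 cm guideline. Bony-landmark markers carry
static weight 5, upper-body markers 1.

**Inverse kinematics** is a per-frame damped Gauss-Newton weighted
least-squares fit with warm starts, analytic marker Jacobians, and a
monotone-objective safeguard. Segment-identifying markers outweigh bony
landmarks (the reverse of scaling). Error guidelines: RMSE below 2 cm,
worst marker below 2–4 cm; frames above threshold are reported, and
under-constrained frames hold the previous pose.

**Inverse dynamics** applies the measured ground reactions at their centres
of pressure and returns per-coordinate generalized forces; the forces at the
pelvis coordinates are the residuals ("hand-of-god" forces), judged against
the standard 1% guideline. Velocities and accelerations missing from a
trajectory are obtained by 4th-order central differences; a zero-lag
Butterworth low-pass (with odd-reflection end padding) is available for
noisy data but is **off by default** — gait kinematics contain real content
near 5 Hz, and filtering clean angles at 6 Hz corrupts accelerations far
more than it helps.

**Residual reduction** adjusts a uniform segment-mass factor and the torso
centre-of-mass fore-aft offset by a damped two-variable Newton iteration on
the mean vertical residual force and mean residual moment. On synthetic
trials it recovers a deliberately injected ±2% mass error to much better
than ±0.2% and reports the signed total mass change.

**Modified static optimization** solves, per frame, for the 76 muscle
activations and the two prosthesis-actuator controls that reproduce the ID
torques while minimizing the sum of squared activations plus squared
actuator controls. Actuator "activation" is the normalized control
(torque over optimal torque), making both cost terms dimensionless. The
pelvis coordinates are excluded from the equality set — their forces are
residuals, not muscle demands. The problem is a strictly convex QP with a
unique solution; infeasible demands are flagged and solved in a
least-squares sense, never silently clipped.

**Modified computed muscle control** drives a forward simulation from the
reference kinematics. Per step:

1. a proportional-derivative look-ahead law forms desired accelerations,
   with muscle-coordinate gains kp = 100, kv = 20 and prosthesis-coordinate
   gains kp = 1000, kv = 90, and a 1 ms look-ahead;
2. a control allocation QP distributes the demand over muscles (cost
   `(a/F0)^2`), the two ideal actuators (optimal torque 1 MN·m, hence nearly
   free), and reserve actuators at every coordinate (optimal torque 1 N·m,
   hence heavily penalized), against a weighted acceleration-mismatch
   penalty (default weight 1 per coordinate; a fast-target mode enforces
   the match as a hard constraint instead);
3. muscle activations advance through their first-order dynamics — the
   allocated muscle variables are neural excitations, and the allocator
   accounts for the exact one-step activation response (iterating the
   rise/fall branch to a fixed point) so that commanded and realized
   accelerations agree — while actuator torques apply instantaneously;
4. the state integrates semi-implicitly at 1 ms.

Initial activations are warm-started from an allocation solve at the first
frame. Reserve torques are logged every step; their peak on muscle-driven
joints relative to the peak prosthesis torque is the controller's health
metric and stays orders of magnitude below one in the packaged conditions.

### The activation lower bound

The allocation exposes `activation_min`. The package default is 0.02, the
conventional computed-muscle-control floor. A floor as high as 0.2 — which
appears in some descriptions of this controller family — forces 20%
co-contraction of antagonist groups; combined with the 40 ms deactivation
lag and the conservative rigid-tendon capacity, that makes sub-degree
tracking unattainable in this planar replica (experiments show mean errors
of several degrees and saturation spirals), contradicting the sub-0.2°
tracking such controllers are reported to achieve. Users can select
`run_config(mcmc = list(activation_min = 0.2))` to study that regime.

## The synthetic trial generator

`generate_consistent_trial()` emulates a treadmill motion-capture session:

* **Kinematics.** Smooth periodic joint waveforms (truncated Fourier series,
  six harmonics — four are too few to hold the prosthetic knee's flat stance
  band together with its ~44° swing bump) with gait-like phasing: stance
  60%, swing 40%, left leg half a cycle out of phase. The amputee variant
  keeps the prosthetic knee essentially extended (within 0–5°) through
  stance, the passive prosthetic ankle has limited plantarflexion, and the
  contralateral ankle shows the extra plantarflexion typical of walking on a
  passive foot. Default cycle 1.25 s at 0.7 m/s — a realistic, deliberately
  unhurried amputee gait chosen so that all joint demands stay within the
  rigid-tendon muscle capacity; pelvis sway amplitudes were chosen once so
  the whole-body moment balance keeps the centre of pressure within the
  stance foot.
* **Markers.** 28 plug-in-gait-style markers by forward kinematics at
  100 Hz, with optional isotropic Gaussian noise (seeded, reproducible).
* **Ground reactions.** At 1000 Hz, the exact net external wrench required
  by whole-body Newton-Euler balance is computed frame by frame and assigned
  to the scheduled stance foot at the zero-moment-point centre of pressure
  (clamped to the foot extent, any remainder carried as free torque), with a
  linear load transfer during double support so threshold-based event
  detection lands within one camera frame of the schedule. Inverse dynamics
  of a generated trial therefore returns pelvis residuals at numerical zero
  — by construction, not by fitting.

What the generator does *not* emulate: soft-tissue artefact, marker
occlusion patterns, force-plate noise and drift, out-of-sagittal motion, and
the double-hump vertical GRF shape (consistency, not waveform realism, is
the design goal). Passing the packaged tests therefore demonstrates the
correctness of the pipeline's mechanics and optimization on clean,
self-consistent data — not robustness to every artefact of real motion
capture.

## Numerical choices

* **QP solver.** Both redundancy problems are strictly convex QPs with box
  constraints; equalities are enforced by an augmented-Lagrangian outer loop
  on row-normalized constraints over a primal active-set inner solver with
  Jacobi equilibration (effector capacities span six orders of magnitude).
  Feasible-frame equality residuals sit at ~1e-9; unattainable demands
  return an "infeasible" status with the violation.
* **Problem sizes.** The packaged tests and the acceptance script use one to
  two gait cycles at 100 Hz markers / 1 kHz plates, and full-cycle forward
  simulations at 1 ms — sizes a laptop handles in seconds to tens of
  seconds.
* **Determinism.** The only random element anywhere is marker noise, drawn
  from a caller-supplied seed with the global RNG state restored; pipeline
  reruns under a fixed seed are byte-identical.

## Known limitations

Planar dynamics cannot represent hip ab/adduction or rotation moments, so
frontal-plane compensations seen in real amputee gait are out of scope. The
constant moment arms ignore their posture dependence. The rigid tendon
understates plantarflexor capacity at push-off. Ground reactions are always
inputs; there is no contact model, so simulations cannot predict novel
footfalls. The residual-reduction parameterization (uniform mass factor plus
torso COM shift) is intentionally low-dimensional.
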