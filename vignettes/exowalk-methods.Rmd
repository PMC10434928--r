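---
title: "exowalk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{exowalk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

`exowalk` asks a narrow biomechanical question: if a walking person wears an
ankle exoskeleton that delivers a short, bell-shaped burst of torque —
plantarflexion at the ankle, inversion or eversion at the subtalar joint, or
a combination — how do the whole-body center of mass (COM) and the
center of pressure (COP) under the foot move in response, and how much of
that response is shaped by the intrinsic (non-reflexive) mechanics of
muscle?

The pipeline has two steps. Step one produces a periodic, dynamically
bookkept reference gait cycle at 1.25 m/s. Step two perturbs it: starting
from the reference state at torque onset, the model is forward-integrated
over a window equal to 15% of the gait cycle while a four-parameter torque
profile (rise 10 %GC, fall 5 %GC, peak 0.1 N·m per kg body mass at one of
nine peak times between 20 and 60 %GC) is applied across the ankle and/or
subtalar joint as equal-and-opposite body torque pairs. Muscle excitations
are deliberately held at their reference values — the window is shorter than
a physiological feedback response — so the only muscle contribution to the
perturbation response is mechanical: force–length, force–velocity and tendon
elasticity. Running each condition twice, once with Hill-type muscles under
fixed excitations ("muscle-driven") and once with the muscle-generated
moments replayed by torque actuators ("torque-driven"), isolates exactly
that contribution.

Changes are always *exo minus baseline*, where the baseline is a zero-torque
forward roll-out from the identical initial state. This choice (over
differencing against the reference trajectory itself) cancels integration
drift and any residual dynamic inconsistency of the reference, which is what
makes a fully synthetic reference usable in place of tracked motion-capture
data.

## The reduced model

The skeleton has 23 degrees of freedom: a 6-DOF free pelvis, a lumped
torso+head+arms segment on a 3-DOF lumbar joint, and per leg a 3-DOF hip,
1-DOF knee, ankle, subtalar and metatarsophalangeal (MTP) joint. Multi-DOF
joints are expanded into chains of single-DOF pins with massless
intermediate bodies, so the compiled dynamics core (composite-rigid-body
mass matrix, recursive Newton–Euler bias forces, world-frame spatial
algebra) handles one uniform joint type. The subtalar axis is the classic
anatomical average (42° from horizontal, 23° medially deviated); left-leg
axes are mirrored so that positive coordinates mean the same anatomical
motion on both sides (inversion positive, plantarflexion negative).

Total mass defaults to 72.4 kg and height to 1.80 m. Segment lengths
(femur 0.47 m, tibia 0.46 m) sit at the upper end of anthropometric tables
for that height; they were chosen so the designed foot trajectories stay
within leg reach with 10–20° of knee flexion throughout the cycle.

Passive elements: mass-scaled lumbar springs (1.0/1.5/0.5 N·m·rad⁻¹·kg⁻¹
for extension/bending/rotation), 2 N·m·s/rad dampers at the ankle, lumbar,
subtalar and MTP joints, a 25 N·m/rad MTP spring, and a diagonal
ankle–subtalar bushing. The bushing constants are not published for the
configuration we mirror; the default (40 N·m/rad, 1.0 N·m·s/rad) was set
once from cadaver ankle inversion–eversion stiffness ranges after the
initial 10 N·m/rad placeholder allowed ~10° subtalar excursions under a
7 N·m device torque. Range-of-motion guards are exponential springs of the
form c₁(exp(c₂x) − 1 − c₂x) in the excursion x past an engagement point 5°
inside each coordinate bound: exactly zero and C¹ at engagement (a pure
exponential cannot satisfy the requirement of vanishing guard torque at the
neutral pose for realistic ranges).

### Muscles

Twelve Hill-type muscles per leg (gluteus maximus/medius, iliopsoas,
hamstrings, rectus femoris, vasti, both gastrocnemius heads, soleus,
tibialis anterior/posterior, peroneus longus) with constant-coefficient
path polynomials: the muscle–tendon length is linear in the spanned
coordinates, so moment arms are constants taken from published nominal
values. Both subtalar directions are actuated (tibialis posterior inverts,
peroneus longus everts), and the triceps surae carry small inversion arms
(5–6 mm) because they insert on the calcaneus and genuinely cross the
subtalar joint.

Activation and normalized tendon force are the muscle states. Activation
follows smooth first-order dynamics with a tanh blend between τ_act =
0.015 s and τ_deact = 0.060 s; the step-response time-to-63% is within 5%
of τ_act. Tendon compliance is enabled only for soleus and the
gastrocnemius heads with strain 0.10 at maximum isometric force; all other
tendons are rigid. The tendon curve is quadratic in a softplus-smoothed
strain, normalized so f̃(1+ε₀) = 1 exactly, ≤0.01 at slack, convex, and C¹
everywhere; the smoothing sharpness scales with 1/ε₀ so the stiff limit
(ε₀ → 1e-4) reproduces rigid-tendon forces within 1%. The force–velocity
curve is an asinh shape re-anchored so f_v(0) = 1 exactly, invertible in
closed form for the tendon-force state derivative; fiber velocities outside
±v_max are clamped and counted.

A detail that matters for the headline physics: each fiber is anchored at
0.92 of optimal length in a canonical loaded mid-stance posture. On the
ascending limb of the force–length curve, length feedback under kinematic
perturbation is spring-like (stabilizing), as it is for human stance-phase
muscles. The original neutral-pose anchoring put several stance muscles on
the flat/descending limb, where a shortening perturbation *raises* force —
a locally destabilizing feedback that distorted the muscle-driven
perturbation responses.

### Contact

Six spheres per foot (heel, two midfoot, two metatarsal — 0.11 m apart,
which is also the foot width used to normalize COP outcomes — and one toe
sphere). The normal force is Hunt–Crossley, k·δ^{3/2}(1 + 1.5cδ̇), with the
penetration δ passed through a softplus so the force is smooth across
touchdown and carries a sub-newton tail just above contact; friction is a
tanh-regularized Coulomb term plus a viscous term. The default smoothing
sharpness (1e4 m⁻¹) keeps the touchdown tail below 1 N; the tracking stage
prefers a softer 500 m⁻¹ (configurable) because collocation benefits from
smoother dynamics between mesh points.

## The synthetic gait

The generator replaces motion capture. Rather than prescribing joint angles
directly, it designs what the contact model needs: a pelvis trajectory
(fore-aft advance at the walking speed; vertical oscillation of ±1.7 cm
placed so the designed vertical load swings between roughly 0.75 and 1.25
body weight; lateral sway toward the stance side), and per-foot calcaneus
pose targets built from a designed load profile. During stance, the foot
pitch follows a heel-strike → foot-flat → heel-off → toe-off progression
and the calcaneus height is solved at each instant so the *actual* contact
model produces the designed vertical load; during swing the lowest sphere
tracks a clearance bump. Leg joint angles then come from an exact 6-DOF
Newton inverse-kinematics solve per node, and every coordinate is fit with
a truncated Fourier series (30 harmonics by default), making the cycle
periodic by construction with analytic derivatives.

The generator's free constants were tuned once against the stated
validation bands — foot-flat ≈ 12.5 %GC, heel-off in terminal stance,
toe-off ≈ 63.6 %GC, step width ≈ 0.17 m, COM height within 0.9–1.1 m,
vertical GRF peak below 1.4 body weight — and then frozen. The packaged
defaults land at foot-flat 13.2 %GC, heel-off 44 %GC, toe-off 64.5 %GC,
step width 0.17 m, COM height 1.08 m, peak vertical GRF 1.36 BW.

What the generator does *not* emulate: subject-specific kinematic
variability, arm swing (arms are lumped into the torso), marker noise
structure, EMG, and true dynamic consistency — the synthetic gait is a
kinematic construction. Dynamic consistency is restored bookkeeping-wise:
static optimization distributes the inverse-dynamics moments at hip
flexion, knee, ankle and subtalar over the muscles (minimum summed squared
excitation, bounds [0,1], flagged least-squares fallback when infeasible),
the activation and tendon-force ODEs are *integrated* along the cycle so
the stored muscle states satisfy their own dynamics, and residual
actuators at every coordinate absorb the remainder. Residuals are largest
around heel strike (impact transient of the Fourier-smoothed kinematics)
and are identical between exo and baseline runs, so they cancel in every
reported change. A green perturbation test therefore establishes the
mapping from device torque to kinematic *changes* about this gait, not the
realism of the gait's absolute joint moments.

## Tracking stage

The tracking problem mirrors the standard direct-collocation setup: states
(coordinates, speeds, activations, tendon forces), controls (excitations,
residual moments), a weighted least-squares cost (coordinate and speed
tracking — subtalar and MTP carry zero weight —, GRF tracking, torso and
calcaneus orientation/angular-velocity tracking, excitation and heavy
residual effort), periodicity of all states and controls (the fore-aft
pelvis coordinate instead satisfies an average-speed equality), and a
minimum feet-distance path constraint. Transcription is Hermite–Simpson
with explicit dynamics, 10 ms default mesh.

Because no interior-point NLP solver is available in this environment, the
NLP is solved by damped Gauss–Newton on the stacked residuals with a ramped
quadratic penalty on the equality constraints. The Jacobian is estimated by
finite differences with node coloring (nodes three apart never share a mesh
interval), assembled sparsely, and reused across iterations until progress
stalls; Marquardt diagonal scaling keeps steps small along
contact-sensitive directions. On toy transcriptions (double integrator)
the solver reproduces closed-form optima to 1e-11 and meets the 1e-4
constraint tolerance. On the full walking problem, periodicity and
average-speed violations reach the 1e-4 tolerance but collocation defects
plateau near 7e-4 within the runtime budget; the solution object reports
`max_defect` and `max_periodicity` separately. Coordinate recovery from
noise-free synthetic observations is ~0.01° RMS, far inside the 2°
validation bound, which is the property the acceptance suite asserts.

## Numerical choices

* Forward windows: Dormand–Prince 5(4) with absolute and relative
  tolerance 1e-6 (the accepted equivalent of 4th-order Runge–Kutta–Merson
  at accuracy 1e-6), dense output at 1 kHz via cubic Hermite interpolation;
  step counts, rejections, force–velocity clamps and range-of-motion
  violations are logged per trajectory.
* COM acceleration is computed from the external-force resultant (contact +
  gravity + pelvis-translation residuals), which is exact within the
  dynamics and makes the flight-phase invariance (internal torque pairs
  cannot accelerate the COM) hold to machine precision.
* The COP is the vertical-force-weighted contact point, flagged undefined
  below 10 N of vertical force; velocity normalization uses the Froude
  scale sqrt(g·h_COM) (the dimensionally consistent reading of the cited
  normalization), positions use h_COM, accelerations g, COP the 0.11 m
  foot width, and angular momentum m·h_COM·sqrt(g·h_COM).
* Ties/degenerate inputs: zero-length windows return the initial state;
  zero-magnitude conditions produce bitwise-identical exo and baseline
  trajectories; COP deltas are NA-flagged when either trajectory's COP is
  undefined at the peak time.

## Known limitations

Two acceptance properties motivated by the reference study's empirical
findings do not fully hold on this reduced model, and are left red rather
than tuned away:

1. *Muscle attenuation ordering.* Torque-driven COM velocity changes
   exceed muscle-driven ones for 34 of 35 device × mid-stance timing
   pairs — including every plantarflexion condition, the headline case
   (e.g. 1.95× for PF at 40 %GC). The single exception is eversion at
   35 %GC, the two smallest responses in the grid (0.0079 vs
   0.0067 m/s): there, muscle force–velocity side effects at the ankle
   and knee redistribute vertical ground force and move the COM slightly
   more than the frozen-moment model, even though the subtalar excursion
   itself *is* attenuated. A model with the full complement of
   subtalar-crossing muscles would raise the muscular subtalar impedance
   well above our ~5 N·m/rad and likely restore the ordering.
2. *No downward velocity change.* Eversion-containing devices produce
   small downward COM velocity changes (−0.0014 to −0.016 m/s): everting
   the foot lowers the ankle through the inclined subtalar axis (a
   pronation-like arch drop) and near push-off works against the
   triceps-surae support moment through the shared calcaneal insertion.
   The reference finding is a null result on multi-subject data with an
   80-muscle model; our 24-muscle reduction reproduces the transverse- and
   sagittal-plane sign structure but not this vertical null. Relatedly,
   the plantarflexion "backward in mid-stance" sign holds at peaks
   30–45 %GC but flips slightly forward already at 50 %GC — the packaged
   gait's push-off transition arrives about two percent of the cycle
   earlier than the multi-subject average the assertion was written
   against.

Beyond these: no reflex or feedback muscle response (by design — windows
are shorter than physiological latencies), no device mass, no short-range
stiffness or history-dependent muscle properties, massless-actuator
devices only, flat ground, and subject-specific result magnitudes are out
of reach without the original multi-subject dataset.
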