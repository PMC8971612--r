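---
title: "Predictive sit-to-stand simulation: model, cost, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive sit-to-stand simulation: model, cost, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the plant model
and its assumptions, the objective that engenders standing up, the search
and tracking machinery, the places where the design was genuinely open and
what was decided, and the limitations a user should keep in mind.

## The plant

The skeleton is a planar three-link chain - shank, thigh, torso+head+arms
(HAT) - hinged at the ankle, knee and hip, with the foot welded to the
ground. Angles are zero upright; ankle dorsiflexion, knee flexion and hip
flexion are positive. The lumbar joint is locked at -10 degrees (lumbar
extension positive), which the model realizes as a fixed 10-degree forward
tilt of the HAT segment. Anthropometry represents a 75 kg, 170 cm adult.
Because the motion is sagittally symmetric, both legs act as one effective
leg: the shank and thigh carry twice the single-limb mass fractions of
standard anthropometric tables (de Leva proportions), and the foot
(2.05 kg) rests on the ground. Segment lengths, centre-of-mass offsets and
inertias are configuration entries with documented defaults; so is every
other number below.

Eight lumped Hill-type musculotendon units drive the chain: iliopsoas
(ILPSO), gluteus maximus (GMAX), biarticular rectus femoris (RF),
biarticular hamstrings (HAMS), vasti (VAS), biarticular gastrocnemius
(GAS), soleus (SOL) and tibialis anterior (TA). Maximum isometric forces
default to 2697.3, 3337.6, 2191.7, 4105.5, 9594.0, 4690.6, 7925.0 and
2116.8 N respectively and are multiplied uniformly by `strength_scale` to
model strength deficits (0.8 = 20% deficit, and so on). Force generation
uses a rigid tendon: a Gaussian active force-length curve (width 0.45),
a Hill force-velocity curve (shortening asymptote `af = 0.25`, eccentric
plateau 1.4, C1-continuous at zero velocity), an exponential passive toe
(`kpe = 4`, strain scale 0.6) and first-order activation dynamics
(`act_tau = 0.01` s, `deact_tau = 0.04` s). Moment arms default to
constants per spanned joint (cubic polynomials in the joint angle are
supported); path length and arms are consistent by construction
(`dL/dq_j = -r_j`). Fiber lengths are referenced so each muscle sits at its
optimal length at the mid-range posture `q_ref = (0.14, 1.0, 0.6)` rad. The
hip entry is deliberately nearer upright: in deep hip flexion (sitting) the
hip extensors then carry realistic passive tension, which both matches the
seated-stretch feel of real tissue and gives the trunk a stable passive
equilibrium on the chair - with zero excitation the model stays seated for
the whole horizon, which is also the optimizer's initial guess.

Joint ranges (ankle -40..30, knee 0..140, hip -30..120 degrees) are
enforced by exponential limit springs (scale 1 N m, rate 20 per rad) that
are exactly zero inside the range. Two damping terms exist: a small
constant joint damping (1 N m s/rad, passive tissue) and a limit damping
(5 N m s/rad) active only beyond a limit, representing ligament
dissipation; without the latter, a passive trunk flopping onto the hip stop
bounces hard enough to violate the seat friction cone. The hip-range
reading of "extension below 30 degrees" is taken as -30 degrees in our
convention; both readings are reachable through the configuration.

While seated, the femur head is pinned to the seat point (the hip position
implied by the sitting posture, ankle 12 / knee 85 / hip 85 degrees) by a
two-dimensional point constraint solved with Lagrange multipliers; the
multiplier pair is the seat reaction. The constraint is removed permanently
the first time the reaction turns non-compressive or leaves the friction
cone (`mu = 0.8` by default for both seat and ground; `mu` has no published
value and is a required, documented configuration field). Ground reaction
force and moment are recovered from whole-body Newton-Euler bookkeeping;
the zero-moment point follows from the recorded wrench
(`zmp_x = ref_x - moment / F_y`, with the stored moment being what the foot
applies to the ground about the point under the ankle).

## The objective

A roll-out is scored by `phi_total = sum(w_i * phi_i)` over ten terms with
default weights `w = (800, 1.2, 175, 70, 5, 10, 0.1, 1000, 6, 0.3)` and
`tau = t_max / 8`: (1) the ratio of final to initial COM distance from the
standing goal; (2) the seat force integrated under an exponential weight
that integrates to one over the roll-out (late contact costs more), gated
by `1 - alpha`; (3, 4) mean squared activations and activation rates
(central differences of the recorded activations); (5) the assistance-force
magnitude integral; (6) integrated absolute limit-spring torques; (7) the
worst slip-condition violation; (8) the worst ZMP excursion from the foot
midpoint; (9) terminal joint speeds; (10) deviations of the vertical ground
force extrema (after seat release) and terminal value from body weight.
`alpha` is the fraction of the seated-to-standing COM distance covered.
Terms 7-10 are multiplied by `alpha` so that early, unstable candidates can
be explored cheaply. Quadrature is trapezoidal on the stored 1 ms grid. Two
degenerate cases are defined explicitly: when the seat never releases, the
term-10 window collapses to the final sample; a zero-duration roll-out has
a single sample and zero integrals. The printed form of term 8 is ambiguous
between a maximum and a time integral; the maximum is the default and the
integral is available (`compute_cost(zmp_term = "integral")`) - in our
sweeps the two give nearly identical outcomes.

## Search

The decision vector holds one gene per actuator per 0.1 s node (the value
at time zero is the default activation, 0.05 for muscles and 0 for
assistance, and is not optimized) plus the duration `t_f`: 129 genes
unassisted, 161 assisted. Genes live on [0, 1]; `t_f` is mapped affinely
onto `[0.8, 1.6]` s. The lower duration bound is a deliberate physiological
choice: observed STS takes roughly a second, and if much shorter roll-outs
are admissible the search reliably discovers a degenerate optimum - hop off
the seat and end the simulation mid-fall before any progress-gated penalty
can bite. Bounds are enforced by clamping at decode time plus a quadratic
out-of-bounds penalty so the sampler stays informed.

The optimizer is an active CMA-ES (negative recombination weights)
implemented in the package and unit-tested on analytic functions. Defaults
follow standard practice: population `4 + floor(3 log n)`, initial step
0.15 on the unit cube (0.25 is used in the bundled acceptance protocol), a
stagnation restart when the best cost improves by less than 1.0 over 250
generations (first possible at generation 251), restarts recentred on the
best-seen candidate with covariance and step size reset, and a cap of 4000
generations per run with four restarts at full budget. A separable variant
(`optimizer_config(diagonal = TRUE)`) adapts only the coordinate variances;
in the 129-dimensional problem under reduced budgets it reaches clearly
better costs than the full covariance update and is what the bundled
acceptance protocol uses. Evaluations are sequential, so a fixed seed gives
bit-identical histories.

## Tracking and failure diagnosis

The tracker steps through a reference kinematic trajectory (spline
derivatives supply reference velocity and acceleration): a PD law with
look-ahead `T` (defaults `kp = 100` 1/s^2, `kv = 20` 1/s, `T = 0.01` s, a
critically damped pairing) produces desired accelerations, and a
fast-target static optimization distributes them: minimize the sum of
squared controls subject to the achieved accelerations matching, with
muscle controls in [0, 1] scaling the instantaneous maximum *active* force
at the current fiber length and velocity, and ideal reserve actuators
(default 1 N m per unit control) guaranteeing feasibility. Passive fiber
forces are applied as an always-present baseline rather than scaled by the
control - passive tension exists regardless of excitation, and this keeps
tracked antagonist loads physical; the stage remains a convex program,
solved exactly by a KKT active-set iteration (unit-tested against an
independent quadratic-program solver). Recorded seat and assistance forces
are supplied as external forces because the tracker runs without the seat
constraint. Reserve controls are unbounded by default so the equality
constraints always stay feasible; muscle saturation then shows up as
reserve torque. Diagnosing weakness compares two tracked setups with
complementary reserve pricing (one joint's reserve cheap, the other's
expensive); the joint whose reserve torque persists under both pricings -
scored as the smaller of its two peak magnitudes - is implicated, with ties
reported as no finding.

## Numerical choices

Equations of motion are the closed-form planar chain dynamics (derived once
symbolically, implemented in compiled code, and cross-checked in the test
suite against compound-pendulum closed forms, energy conservation and
momentum bookkeeping). Integration is fixed-step RK4 at 1 ms with the
seat-release test applied at step boundaries, which makes roll-outs exactly
reproducible; the seat constraint uses mild Baumgarte stabilization
(beta = 20 1/s). Activations are clamped to [0, 1] after each step.
Roll-outs whose joint speeds pass 50 rad/s are truncated and flagged, and
the cost function still scores the partial record so the optimizer can rank
failures. Initial muscle states come from equilibration at activation 0.05
(rigid tendon: a kinematic identity; an elastic-tendon equilibration with a
linear tendon at 3.3% iso-force strain is provided for initialization and
verified against bisection, but the roll-out itself is rigid-tendon).

## What the synthetic inputs do and do not emulate

All test inputs are generated in code: model configurations across the
strength-deficit sweep, band-limited EMG-like bursts with known
maximum-voluntary-contraction peaks, minimum-jerk seated-to-upright
reference kinematics, and a reference STS controller produced by the
package's own optimizer at 40% strength deficit
(`inst/extdata/controls_scale060_optimized.csv`). These capture the
structure of laboratory recordings (sampled joint angles, sEMG channels,
seat/ground force channels) but none of their messiness: no marker noise or
soft-tissue artifact, no inter-trial variability, no real co-contraction
idiosyncrasies. Passing tests therefore demonstrate internal correctness
and the method's qualitative behavior, not validity against any particular
subject.

## Known limitations

* **Search budget.** The bundled protocol (500 generations plus one
  restart, ~18k roll-outs per strength level) is one to two orders of
  magnitude below the full-budget setting the method is designed for. At
  this budget the optimizer reliably stands the model most of the way up -
  the progress scalar converges to roughly 0.85-0.91 across strength scales
  1.0-0.4, with the seat released and the three movement phases ordered -
  but often stops just short of the 0.9 completion mark: under the default
  weights, the braking transient needed to finish and settle (activation
  rates, feet-force deviations) costs about as much as the remaining
  completion reward, so near-complete candidates form a broad, flat
  optimum. Similarly, the assisted 80%-deficit model needs a coordinated
  horizontal-plus-vertical assistance pattern that this budget does not
  discover from the seated initial guess. Users reproducing full-budget
  behavior should raise `max_generations` and `n_restarts`.
* **Strength-to-weight ratio.** The model carries the full 75 kg body on
  one effective leg whose muscle strengths are single-limb values, so it is
  relatively weaker than a bilateral human; failure thresholds shift
  accordingly, and the binding weakness when tracking a strong reference
  with a very weak model appears at the hip as well as the knee.
* The foot is welded (no heel rise or slide), the seat is a point
  constraint (no contact patch), the lumbar joint is locked, and the model
  is strictly planar. Closed-loop control, sensory noise and delay are out
  of scope.
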