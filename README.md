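# sitstand

Predictive simulation of the sit-to-stand (STS) transition with muscle
strength deficits and assist-as-needed external forces.

## The problem

Rising from a chair is one of the most strength-demanding tasks of daily
life, and lower-extremity weakness is a leading reason people lose the
ability to do it. Separating the effect of strength from everything else
(balance, pain, chair geometry) is hard experimentally, so this package
synthesizes STS movements *de novo* from a musculoskeletal model: it searches
for the muscle excitation trajectories that let a seated planar human model
stand up, at full strength and with its maximum isometric muscle forces
scaled down in steps of 20%. When the unassisted model can no longer rise,
external assistance forces at the torso can be optimized together with the
muscles, yielding assist-as-needed force profiles. A tracking tool with
reserve actuators diagnoses which muscle group's weakness is responsible for
failure. The intended audience is biomechanists and rehabilitation-device
designers.

## The model and method

* **Plant** — a planar 3-degree-of-freedom linkage (ankle, knee, hip; foot
  welded to the ground) representing a 75 kg / 170 cm adult with both legs
  lumped into one effective leg, driven by eight Hill-type musculotendon
  actuators (ILPSO, GMAX, RF, HAMS, VAS, GAS, SOL, TA; rigid tendon,
  Gaussian active force-length, Hill force-velocity, exponential passive
  curves, first-order activation dynamics). Nonlinear torsional springs
  restrict the joints to physiological ranges. While seated, the femur head
  is pinned to the chair by a point constraint solved with Lagrange
  multipliers; the constraint is removed permanently the first time its
  reaction turns non-compressive or violates the friction cone
  (`|F_x| > mu * F_y`).
* **Controller** — open-loop piecewise-linear excitations with 0.1 s nodes
  over a 1.6 s horizon, plus the movement duration `t_f`: 129 decision
  variables unassisted, 161 with the two 0-200 N assistance actuators.
* **Objective** — `phi_total = sum_i w_i phi_i` over ten terms: COM distance
  to the standing goal, exponentially time-weighted seat force, squared
  activations and activation rates, assistance magnitude, limit-spring
  torques, slip and zero-moment-point (ZMP) violations, terminal joint
  speeds, and vertical ground-force deviations from body weight. Terms 7-10
  are gated by the STS-progress scalar
  `alpha = 1 - min(d(Cf,G), d(C0,G)) / d(C0,G)`.
* **Search** — active CMA-ES (own implementation, with an optional separable
  covariance update for tight budgets) with the seated posture as initial
  mean, stagnation-triggered restarts recentred on the best candidate.
* **Diagnosis** — computed-muscle-control style tracking: PD desired
  accelerations, then a fast-target static optimization
  (`min sum(e_i^2)` s.t. achieved accelerations match) over muscles plus
  ideal reserve actuators; persistent reserve torque at a joint under
  complementary reserve pricings implicates that joint's muscles.

## Worked example

```r
library(sitstand)

# full-strength model: a zero-excitation roll-out rests on the chair
model <- build_model()
layout <- control_layout(model)
sim0 <- simulate_sts(model, decode_controls(sitting_guess(layout), layout))
sim0
#> STS roll-out: 1601 samples over 1.600 s
#>   seat never released
#>   final COM (-0.105, 0.707) m, |qdot|_max 0.94 rad/s

# optimize an STS trajectory for a 40% strength deficit at a reduced budget
weak <- build_model(default_model_config(strength_scale = 0.6))
opt <- optimize_sts(weak, config = optimizer_config(
  max_generations = 500, n_restarts = 1,
  initial_sigma = 0.25, diagonal = TRUE, seed = 7))
opt
#> STS trajectory optimization: 1000 generations over 2 run(s)
#>   best cost 411.773, alpha 0.9139, t_f 1.033 s
#>   seat released at 0.352 s

segment_phases(opt$best_result)
#> $t_phase1_end  0.352   (seat release)
#> $t_phase2_end  0.510   (maximal hip flexion)
#> $t_phase3_end  1.033   (upright)
```

The printed `alpha` is the fraction of the seated-to-standing
centre-of-mass distance covered by the final state (1 = fully standing),
`t_f` the movement duration and the phases follow the conventional
flexion / rise / extension split of STS.

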