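#' Default model configuration
#'
#' Returns the full configuration of the planar sit-to-stand model: a
#' three-segment linkage (shank, thigh, torso+head+arms) welded to the ground
#' at the foot, eight lumped Hill-type musculotendon actuators, nonlinear
#' joint-limit springs, a point-on-point seat constraint at the femur head,
#' and optional horizontal/vertical assistance forces at the torso centre of
#' mass.
#'
#' The model represents an average adult male of 75 kg and 170 cm. Both legs
#' act as a single effective planar leg, so leg-segment masses are doubled
#' relative to single-limb anthropometric tables (de Leva proportions); the
#' total segment mass including the fixed foot equals the body mass. Maximum
#' isometric muscle strengths follow the lumped muscle groups ILPSO, GMAX,
#' RF, HAMS, VAS, GAS, SOL and TA. Segment geometry, inertias, moment arms,
#' fiber parameters, limit-spring coefficients and the sitting posture are
#' package defaults chosen from standard anthropometric and Hill-model
#' tables; every entry can be overridden via this configuration.
#'
#' Angle conventions: 0 degrees = upright; positive = ankle dorsiflexion,
#' knee flexion, hip flexion. Configuration angles are in degrees (matching
#' the on-disk convention); radians are used in memory by the dynamics.
#'
#' @param strength_scale fraction in (0, 1] multiplying every muscle's
#'   maximum isometric force (1 = no deficit, 0.4 = 60\% deficit).
#' @param assist logical; add the two 0-200 N assistance point actuators.
#' @return nested list with sections `anthropometry`, `segments`, `foot`,
#'   `muscles`, `curves`, `limits`, `chair`, `assist`, `posture`,
#'   `integrator`, plus `gravity`, `strength_scale` and `seed`.
#' @export
default_model_config <- function(strength_scale = 1.0, assist = FALSE) {
  list(
    anthropometry = list(body_mass = 75, height = 1.70),
    gravity = 9.80665,
    strength_scale = strength_scale,
    lumbar_lock_angle = -10,   # degrees, lumbar extension positive
    segments = list(
      shank = list(mass = 6.50,  length = 0.42, com_offset = 0.232, inertia = 0.075),
      thigh = list(mass = 21.20, length = 0.42, com_offset = 0.248, inertia = 0.405),
      torso = list(mass = 45.25, length = 0.55, com_offset = 0.320, inertia = 2.200)
    ),
    foot = list(mass = 2.05, ankle = c(0.0, 0.08), heel_x = -0.08,
                toe_x = 0.17, com = c(0.045, 0.03)),
    muscles = list(
      names    = c("ILPSO", "GMAX", "RF", "HAMS", "VAS", "GAS", "SOL", "TA"),
      f_max    = c(2697.3, 3337.6, 2191.7, 4105.5, 9594.0, 4690.6, 7925.0, 2116.8),
      l_opt    = c(0.18, 0.20, 0.15, 0.18, 0.16, 0.09, 0.08, 0.09),
      l_slack  = c(0.10, 0.12, 0.32, 0.30, 0.13, 0.38, 0.25, 0.22),
      pennation = rep(0, 8),
      v_max    = rep(10, 8),           # optimal fiber lengths / s
      act_tau  = rep(0.01, 8),
      deact_tau = rep(0.04, 8),
      act_default = 0.05,
      # constant moment arms (m); positive = torque in the positive joint
      # direction (dorsiflexion / knee flexion / hip flexion)
      arms = list(
        ILPSO = list(hip = 0.050),
        GMAX  = list(hip = -0.062),
        RF    = list(hip = 0.042, knee = -0.041),
        HAMS  = list(hip = -0.060, knee = 0.032),
        VAS   = list(knee = -0.042),
        GAS   = list(knee = 0.020, ankle = -0.048),
        SOL   = list(ankle = -0.049),
        TA    = list(ankle = 0.037)
      ),
      # posture (rad) at which each path length equals l_slack + l_opt;
      # the hip reference sits nearer upright so the hip extensors carry
      # realistic passive tension in deep hip flexion (seated stretch)
      q_ref = c(0.14, 1.0, 0.6)
    ),
    curves = list(fl_width = 0.45, fv_af = 0.25, fv_fecc = 1.4,
                  fp_kpe = 4, fp_e0 = 0.6),
    limits = list(
      # degrees; plantarflexion and hip extension are negative
      lower = c(ankle = -40, knee = 0, hip = -30),
      upper = c(ankle = 30, knee = 140, hip = 120),
      k = c(1, 1, 1),          # N m torque scale of the exponential curve
      rate = c(20, 20, 20),    # 1/rad stiffening rate beyond the limit
      limit_damping = c(5, 5, 5),  # N m s/rad, active only beyond a limit
      joint_damping = c(1, 1, 1)   # N m s/rad passive tissue damping
    ),
    chair = list(seat_point = NULL,   # NULL: femur-head position at posture
                 mu = 0.8, ground_mu = 0.8, engaged = TRUE),
    assist = list(on = assist, f_max = 200, tau = 0.1),
    # sitting posture: at it, gravity's hip moment is balanced by passive
    # fiber tension plus baseline activation, so the zero-excitation model
    # rests on the chair
    posture = list(sitting = c(ankle = 12, knee = 85, hip = 85)),  # degrees
    integrator = list(dt = 0.001, qdot_cap = 50, baumgarte = 20),
    seed = 1L
  )
}

#' Read a model configuration from YAML or JSON
#'
#' Values present in the file override the package defaults
#' ([default_model_config()]); anything omitted keeps its default.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`)
#' @return configuration list
#' @export
read_model_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_config(default_model_config(), cfg)
}

#' Write a model configuration to YAML
#' @param config configuration list
#' @param path output path
#' @return `path`, invisibly
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# recursive merge: entries of `over` replace entries of `base`
merge_config <- function(base, over) {
  if (!is.list(base) || !is.list(over)) return(over)
  for (nm in names(over)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      merge_config(base[[nm]], over[[nm]])
    } else {
      over[[nm]]
    }
  }
  base
}
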