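#' First-order activation dynamics
#'
#' Rate of change of activation for an excitation input: the activation
#' approaches the excitation with time constant `act_tau` when excitation
#' exceeds activation and `deact_tau` otherwise.
#'
#' @param excitation,activation values in \[0, 1\]
#' @param act_tau,deact_tau time constants (s)
#' @return derivative (1/s)
#' @export
activation_derivative <- function(excitation, activation,
                                  act_tau = 0.01, deact_tau = 0.04) {
  stopifnot(all(excitation >= 0 & excitation <= 1),
            all(activation >= 0 & activation <= 1))
  mapply(cpp_act_deriv, excitation, activation, act_tau, deact_tau)
}

#' Hill-model force curves
#'
#' `active_force_length()` is a Gaussian peaking at 1 for normalized fiber
#' length 1; `force_velocity()` is a Hill hyperbola reaching 0 at maximal
#' shortening (`v_norm = -1`), 1 isometrically and an eccentric plateau
#' (`fecc`, default 1.4); `passive_force_length()` is an exponential toe
#' starting at normalized length 1.
#'
#' @param l_norm fiber length / optimal fiber length
#' @param v_norm fiber velocity / (v_max * optimal length); shortening < 0
#' @param width,af,fecc,kpe,e0 curve coefficients (package defaults match
#'   [default_model_config()])
#' @return dimensionless force multiplier
#' @export
active_force_length <- function(l_norm, width = 0.45) {
  vapply(l_norm, cpp_curve_fl, 0, width = width)
}

#' @rdname active_force_length
#' @export
force_velocity <- function(v_norm, af = 0.25, fecc = 1.4) {
  vapply(v_norm, cpp_curve_fv, 0, af = af, fecc = fecc)
}

#' @rdname active_force_length
#' @export
passive_force_length <- function(l_norm, kpe = 4, e0 = 0.6) {
  vapply(l_norm, cpp_curve_fp, 0, kpe = kpe, e0 = e0)
}

#' Musculotendon force under the rigid-tendon assumption
#'
#' Tendon force `f_max * (a * FL(l) * FV(v) * cos(pennation) + FP(l))`,
#' with `f_max` scaled by the model's strength scale.
#'
#' @param model `planar_model`
#' @param muscle muscle name or index
#' @param activation activation in \[0, 1\]
#' @param l_norm,v_norm normalized fiber length and velocity
#' @return list with `tendon`, `active`, `passive` components (N) plus the
#'   normalized kinematics
#' @export
compute_muscle_force <- function(model, muscle, activation, l_norm, v_norm = 0) {
  i <- muscle_index(model, muscle)
  stopifnot(activation >= 0, activation <= 1)
  acts <- lnorm <- vnorm <- rep(0, nrow(model$muscles))
  acts[i] <- activation; lnorm[] <- 1; lnorm[i] <- l_norm; vnorm[i] <- v_norm
  f <- cpp_muscle_forces(model$cpp, acts, lnorm, vnorm)
  list(tendon = f$tendon[i], active = f$active[i], passive = f$passive[i],
       fiber_length_norm = l_norm, fiber_velocity_norm = v_norm)
}

muscle_index <- function(model, muscle) {
  if (is.character(muscle)) {
    i <- match(muscle, model$muscles$name)
    if (is.na(i)) stop("unknown muscle '", muscle, "'", call. = FALSE)
    i
  } else {
    as.integer(muscle)
  }
}

#' Muscle moment arm
#'
#' Evaluates the configured moment-arm model (constant or cubic polynomial in
#' the spanned joint's angle). Positive arm = torque in the positive joint
#' direction.
#'
#' @param model `planar_model`
#' @param muscle muscle name or index
#' @param q joint angles (rad, length 3)
#' @param joint `"ankle"`, `"knee"` or `"hip"`
#' @return moment arm (m)
#' @export
moment_arm <- function(model, muscle, q, joint) {
  i <- muscle_index(model, muscle)
  j <- match(match.arg(joint, JOINTS), JOINTS)
  if (!model$muscle_spans[i, j])
    stop("muscle '", model$muscles$name[i], "' does not span the ", JOINTS[j],
         call. = FALSE)
  ms <- cpp_muscle_state(model$cpp, q, rep(0, 3))
  ms$arms[i, j]
}

#' Musculotendon path length and lengthening velocity
#'
#' The path length is consistent with the moment-arm model through
#' `dL/dq_j = -r_j(q_j)`; the velocity is the corresponding Jacobian times
#' the joint rates.
#'
#' @param model `planar_model`
#' @param muscle muscle name or index
#' @param q,qdot joint angles (rad) and rates (rad/s)
#' @return list with `length` (m) and `velocity` (m/s)
#' @export
muscle_path <- function(model, muscle, q, qdot = rep(0, 3)) {
  i <- muscle_index(model, muscle)
  ms <- cpp_muscle_state(model$cpp, q, qdot)
  list(length = ms$path_len[i], velocity = ms$path_vel[i])
}

#' Equilibrate the musculotendon units at a posture
#'
#' Computes the initial muscle state at the given activation. With a rigid
#' tendon the fiber length follows directly from the path geometry; with an
#' elastic tendon the fiber length solves the fiber-tendon force balance
#' (linear tendon force-strain, 3.3\% strain at maximum isometric force).
#'
#' @param model `planar_model`
#' @param q posture (rad)
#' @param activation default activation (the roll-outs use 0.05)
#' @param elastic_tendon solve the elastic equilibrium instead of the rigid
#'   kinematic identity
#' @return data.frame per muscle: fiber length, normalized length, tendon
#'   force at zero velocity
#' @export
equilibrate_muscles <- function(model, q, activation = 0.05,
                                elastic_tendon = FALSE) {
  ms <- cpp_muscle_state(model$cpp, q, rep(0, 3))
  mus <- model$muscles
  n <- nrow(mus)
  fiber <- ms$fiber_len
  if (elastic_tendon) {
    for (i in seq_len(n)) {
      fiber[i] <- solve_elastic_fiber(model, i, ms$path_len[i], activation)
    }
  }
  l_norm <- fiber / mus$l_opt
  f <- cpp_muscle_forces(model$cpp, rep(activation, n), l_norm, rep(0, n))
  data.frame(name = mus$name, fiber_length = fiber, l_norm = l_norm,
             tendon_force = f$tendon, active_force = f$active,
             passive_force = f$passive)
}

# root of the fiber/tendon force balance for one muscle (elastic tendon)
solve_elastic_fiber <- function(model, i, path_len, activation,
                                tendon_strain_iso = 0.033) {
  mus <- model$muscles[i, ]
  cfg <- model$config$curves
  fmax <- mus$f_max * model$strength_scale
  cp <- cos(mus$pennation)
  fiber_force <- function(lf) {
    ln <- lf / mus$l_opt
    fmax * (activation * cpp_curve_fl(ln, cfg$fl_width) * cp +
            cpp_curve_fp(ln, cfg$fp_kpe, cfg$fp_e0))
  }
  tendon_force <- function(lf) {
    eps <- (path_len - lf * cp - mus$l_slack) / mus$l_slack
    if (eps <= 0) 0 else fmax * eps / tendon_strain_iso
  }
  resid <- function(lf) fiber_force(lf) - tendon_force(lf)
  lo <- 0.01 * mus$l_opt
  hi <- max(1.99 * mus$l_opt, (path_len - mus$l_slack) / cp + mus$l_opt)
  if (resid(lo) * resid(hi) > 0) {
    # slack path: zero-force state is the equilibrium
    if (tendon_force(lo) == 0 && activation == 0) return(lo)
    if (resid(lo) > 0 && resid(hi) > 0)
      stop("equilibration failed for muscle '", mus$name,
           "': no root in the physiological bracket", call. = FALSE)
  }
  stats::uniroot(resid, c(lo, hi), tol = 1e-12)$root
}
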