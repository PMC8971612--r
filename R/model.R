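#' Build the planar sit-to-stand musculoskeletal model
#'
#' Validates a configuration (see [default_model_config()]) and constructs a
#' `planar_model` object: the three actuated degrees of freedom (ankle, knee,
#' hip), segment and muscle tables, joint-limit springs, the seat constraint
#' anchor, and a packed parameter block for the compiled dynamics.
#'
#' The seat anchor defaults to the femur-head (hip joint) position implied by
#' the configured sitting posture. Muscle maximum isometric forces are the
#' configured values multiplied by `strength_scale`.
#'
#' @param config configuration list; defaults to [default_model_config()].
#' @return object of class `planar_model`
#' @export
build_model <- function(config = default_model_config()) {
  cfg <- config
  segs <- cfg$segments
  stopifnot(length(segs) == 3)
  check_pos <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
      stop("configuration error: '", field, "' must be a positive number",
           call. = FALSE)
  }
  for (nm in names(segs)) {
    s <- segs[[nm]]
    check_pos(s$mass, paste0("segments.", nm, ".mass"))
    check_pos(s$length, paste0("segments.", nm, ".length"))
    if (s$com_offset < 0 || s$com_offset > s$length)
      stop("configuration error: 'segments.", nm,
           ".com_offset' must lie within [0, length]", call. = FALSE)
    if (s$inertia < 0)
      stop("configuration error: 'segments.", nm, ".inertia' must be >= 0",
           call. = FALSE)
  }
  check_pos(cfg$foot$mass, "foot.mass")
  if (cfg$foot$heel_x >= cfg$foot$toe_x)
    stop("configuration error: 'foot.heel_x' must be less than 'foot.toe_x'",
         call. = FALSE)
  total <- sum(vapply(segs, function(s) s$mass, 0)) + cfg$foot$mass
  if (abs(total - cfg$anthropometry$body_mass) > 1e-6)
    stop("configuration error: segment masses (", round(total, 4),
         " kg incl. foot) must sum to 'anthropometry.body_mass' (",
         cfg$anthropometry$body_mass, " kg)", call. = FALSE)
  if (cfg$strength_scale <= 0 || cfg$strength_scale > 1)
    stop("configuration error: 'strength_scale' must be in (0, 1]",
         call. = FALSE)
  if (is.null(cfg$chair$mu) || cfg$chair$mu <= 0)
    stop("configuration error: 'chair.mu' must be a positive friction ",
         "coefficient", call. = FALSE)
  if (any(cfg$limits$lower >= cfg$limits$upper))
    stop("configuration error: joint limits need lower < upper",
         call. = FALSE)

  mus <- cfg$muscles
  n_mus <- length(mus$names)
  if (any(mus$f_max <= 0))
    stop("configuration error: 'muscles.f_max' must be positive",
         call. = FALSE)
  arm <- matrix(0, n_mus, 12,
                dimnames = list(mus$names, NULL))
  spans <- matrix(FALSE, n_mus, 3, dimnames = list(mus$names, JOINTS))
  for (i in seq_len(n_mus)) {
    a <- mus$arms[[mus$names[i]]]
    if (is.null(a) || length(a) == 0)
      stop("configuration error: muscle '", mus$names[i],
           "' spans no joint", call. = FALSE)
    for (j in seq_along(JOINTS)) {
      co <- a[[JOINTS[j]]]
      if (!is.null(co)) {
        co <- c(co, rep(0, 4 - length(co)))[1:4]
        arm[i, (4 * j - 3):(4 * j)] <- co
        spans[i, j] <- any(co != 0)
      }
    }
  }
  # structural checks on the canonical biarticular muscles
  for (m in c("RF", "HAMS")) {
    if (m %in% mus$names && !all(spans[m, c("knee", "hip")]))
      stop("configuration error: '", m, "' must span hip and knee",
           call. = FALSE)
  }
  if ("GAS" %in% mus$names && !all(spans["GAS", c("ankle", "knee")]))
    stop("configuration error: 'GAS' must span knee and ankle", call. = FALSE)

  q0 <- cfg$posture$sitting * pi / 180
  seg_off <- c(0, 0, -cfg$lumbar_lock_angle * pi / 180)
  model <- structure(list(
    config = cfg,
    segments = data.frame(
      name = names(segs),
      mass = vapply(segs, function(s) s$mass, 0),
      length = vapply(segs, function(s) s$length, 0),
      com_offset = vapply(segs, function(s) s$com_offset, 0),
      inertia = vapply(segs, function(s) s$inertia, 0),
      offset = seg_off,
      row.names = NULL
    ),
    foot = cfg$foot,
    muscles = data.frame(
      name = mus$names, f_max = mus$f_max, l_opt = mus$l_opt,
      l_slack = mus$l_slack, pennation = mus$pennation, v_max = mus$v_max,
      act_tau = mus$act_tau, deact_tau = mus$deact_tau, row.names = NULL
    ),
    muscle_arm = arm,
    muscle_spans = spans,
    limits = data.frame(
      joint = JOINTS,
      lower = as.numeric(cfg$limits$lower) * pi / 180,
      upper = as.numeric(cfg$limits$upper) * pi / 180,
      k = as.numeric(cfg$limits$k),
      rate = as.numeric(cfg$limits$rate),
      row.names = NULL
    ),
    gravity = cfg$gravity,
    strength_scale = cfg$strength_scale,
    assist = cfg$assist,
    q0 = unname(q0),
    act_default = cfg$muscles$act_default,
    mass_total = total
  ), class = "planar_model")

  # seat anchor: femur-head position at the sitting posture unless given
  model$cpp <- pack_model(model, seat_point = c(0, 0))
  seat <- cfg$chair$seat_point
  if (is.null(seat)) {
    seat <- cpp_point_kinematics(model$cpp, model$q0, rep(0, 3))$hip
  }
  model$chair <- list(seat_point = as.numeric(seat), mu = cfg$chair$mu,
                      ground_mu = cfg$chair$ground_mu,
                      engaged = isTRUE(cfg$chair$engaged))
  model$cpp <- pack_model(model, seat_point = model$chair$seat_point)
  model
}

# flatten a planar_model into the numeric block the compiled core expects
pack_model <- function(model, seat_point) {
  cfg <- model$config
  mus <- model$muscles
  list(
    seg_m = model$segments$mass,
    seg_L = model$segments$length,
    seg_d = model$segments$com_offset,
    seg_I = model$segments$inertia,
    seg_off = model$segments$offset,
    ankle = as.numeric(cfg$foot$ankle),
    foot_m = cfg$foot$mass,
    foot_com = as.numeric(cfg$foot$com),
    heel_x = cfg$foot$heel_x, toe_x = cfg$foot$toe_x,
    g = model$gravity,
    joint_damping = as.numeric(cfg$limits$joint_damping),
    lim_lo = model$limits$lower, lim_hi = model$limits$upper,
    lim_k = model$limits$k, lim_rate = model$limits$rate,
    lim_damping = as.numeric(cfg$limits$limit_damping),
    seat_point = as.numeric(seat_point),
    seat_mu = cfg$chair$mu, ground_mu = cfg$chair$ground_mu,
    seat_engaged0 = isTRUE(cfg$chair$engaged),
    assist_on = isTRUE(model$assist$on),
    assist_fmax = model$assist$f_max, assist_tau = model$assist$tau,
    n_mus = nrow(mus),
    mus_fmax = mus$f_max * model$strength_scale,
    mus_lopt = mus$l_opt, mus_lts = mus$l_slack, mus_penn = mus$pennation,
    mus_vmax = mus$v_max, mus_taua = mus$act_tau, mus_taud = mus$deact_tau,
    mus_lref = mus$l_slack + mus$l_opt * cos(mus$pennation),
    act_default = rep(model$act_default, nrow(mus)),
    mus_arm = unname(model$muscle_arm),
    mus_qref = as.numeric(cfg$muscles$q_ref),
    fl_width = cfg$curves$fl_width, fv_af = cfg$curves$fv_af,
    fv_fecc = cfg$curves$fv_fecc, fp_kpe = cfg$curves$fp_kpe,
    fp_e0 = cfg$curves$fp_e0,
    dt = cfg$integrator$dt, qdot_cap = cfg$integrator$qdot_cap,
    baumgarte = cfg$integrator$baumgarte,
    q0 = model$q0
  )
}

#' @export
print.planar_model <- function(x, ...) {
  cat("Planar sit-to-stand model (3 DOF: ankle, knee, hip)\n")
  cat(sprintf("  total mass %.2f kg, gravity %.5g m/s^2\n",
              x$mass_total, x$gravity))
  cat(sprintf("  strength scale %.2f (%d%% deficit), assistance %s\n",
              x$strength_scale, round(100 * (1 - x$strength_scale)),
              if (isTRUE(x$assist$on)) "on" else "off"))
  cat(sprintf("  %d muscles: %s\n", nrow(x$muscles),
              paste(x$muscles$name, collapse = ", ")))
  cat(sprintf("  seat anchor (%.3f, %.3f) m, mu = %.2f\n",
              x$chair$seat_point[1], x$chair$seat_point[2], x$chair$mu))
  invisible(x)
}

#' Torque of a nonlinear joint-limit spring
#'
#' Zero strictly inside the configured range; exponentially stiffening and
#' restoring (opposing the excursion) outside; continuous at the limits.
#'
#' @param model `planar_model`
#' @param joint `"ankle"`, `"knee"` or `"hip"`
#' @param q joint angle (rad); may be a vector
#' @return torque in N m (same length as `q`)
#' @export
limit_spring_torque <- function(model, joint, q) {
  j <- match(match.arg(joint, JOINTS), JOINTS)
  lim <- model$limits[j, ]
  vapply(q, function(qi)
    cpp_limit_torque(qi, lim$lower, lim$upper, lim$k, lim$rate), 0)
}

#' Seat-release test
#'
#' The seat constraint is released when the reaction the chair must apply to
#' the femur head turns non-compressive or violates the friction cone.
#'
#' @param seat_reaction 2D force (N) applied by the chair on the femur head
#' @param mu friction coefficient
#' @return `TRUE` if the constraint must be released
#' @export
check_seat_release <- function(seat_reaction, mu) {
  seat_reaction[2] <= 0 || abs(seat_reaction[1]) > mu * seat_reaction[2]
}

#' Forward dynamics at a single state
#'
#' Solves the constrained equations of motion of the 3-DOF linkage. While the
#' seat is engaged the femur-head point acceleration is driven to zero and the
#' Lagrange multiplier pair is returned as the seat reaction.
#'
#' @param model `planar_model`
#' @param state list with `q`, `qdot` (rad, rad/s, length 3) and optionally
#'   `activations`
#' @param muscle_forces optional per-muscle tendon forces (N); overrides
#'   activation-derived forces
#' @param assist_force 2D external force (N) at the torso COM
#' @param ext_joint_torque extra generalized forces (N m, length 3)
#' @param seat_engaged is the seat constraint active?
#' @param locked logical length-3: joints held at zero acceleration
#' @param passive_structures include limit springs and joint damping
#' @return list with `qddot`, `feet_reaction` (`force`, `moment`),
#'   `seat_reaction` (NULL when unconstrained)
#' @export
forward_dynamics <- function(model, state, muscle_forces = NULL,
                             assist_force = c(0, 0),
                             ext_joint_torque = c(0, 0, 0),
                             seat_engaged = FALSE,
                             locked = c(FALSE, FALSE, FALSE),
                             passive_structures = TRUE) {
  act <- state$activations
  out <- cpp_forward_dynamics(model$cpp, state$q, state$qdot,
                              muscle_forces, act,
                              as.numeric(assist_force), c(0, 0),
                              as.numeric(ext_joint_torque),
                              seat_engaged, as.integer(locked),
                              passive_structures)
  list(qddot = as.numeric(out$qdd),
       feet_reaction = list(force = as.numeric(out$feet_force),
                            moment = as.numeric(out$feet_moment)),
       seat_reaction = if (seat_engaged) as.numeric(out$seat_force) else NULL,
       limit_torque = as.numeric(out$limit_torque),
       muscle_tendon_force = as.numeric(out$muscle_tendon_force))
}

#' Inverse dynamics of recorded kinematics
#'
#' Returns the generalized-force residual per degree of freedom when the
#' recorded motion is driven with muscles excluded; seat and assistance
#' forces are supplied as external point forces. The residual therefore
#' equals the net muscle plus passive-structure torque at each joint.
#'
#' @param model `planar_model`
#' @param q,qdot,qddot n x 3 matrices (or length-3 vectors)
#' @param seat_force,assist_force n x 2 matrices (or 2-vectors), default zero
#' @return n x 3 matrix of joint torques (N m)
#' @export
inverse_dynamics <- function(model, q, qdot, qddot,
                             seat_force = NULL, assist_force = NULL) {
  q <- rbind2mat(q); qdot <- rbind2mat(qdot); qddot <- rbind2mat(qddot)
  n <- nrow(q)
  if (is.null(seat_force)) seat_force <- matrix(0, n, 2)
  if (is.null(assist_force)) assist_force <- matrix(0, n, 2)
  out <- cpp_inverse_dynamics(model$cpp, q, qdot, qddot,
                              rbind2mat(seat_force, 2),
                              rbind2mat(assist_force, 2))
  colnames(out$residual) <- JOINTS
  out$residual
}

rbind2mat <- function(x, ncol = 3) {
  if (is.null(dim(x))) matrix(x, 1, ncol) else as.matrix(x)
}

#' Whole-body centre of mass
#'
#' Mass-weighted mean of the segment COM positions, including the fixed foot
#' mass at its ground location. Works for any number of chain segments, so
#' degenerate (single-segment) models are supported.
#'
#' @param model `planar_model`
#' @param q joint angles (rad), one per chain segment
#' @return 2D position (m)
#' @export
compute_com <- function(model, q) {
  com_chain(model, q, rep(0, length(q)))$com
}

#' Whole-body centre-of-mass velocity
#' @param model `planar_model`
#' @param q,qdot joint angles (rad) and rates (rad/s)
#' @return 2D velocity (m/s)
#' @export
compute_com_vel <- function(model, q, qdot) {
  com_chain(model, q, qdot)$com_vel
}

# generic serial-chain COM walk (R-side reference implementation; the
# compiled core has its own 3-segment version, cross-checked in tests)
com_chain <- function(model, q, qdot) {
  segs <- model$segments
  n <- nrow(segs)
  stopifnot(length(q) >= n)
  sgn <- rep(c(1, -1), length.out = n)
  phi <- cumsum(sgn * q[seq_len(n)]) + segs$offset
  phid <- cumsum(sgn * qdot[seq_len(n)])
  base <- as.numeric(model$foot$ankle)
  basev <- c(0, 0)
  msum <- model$foot$mass
  com <- model$foot$mass * as.numeric(model$foot$com)
  comv <- c(0, 0)
  for (i in seq_len(n)) {
    u <- c(sin(phi[i]), cos(phi[i]))
    up <- c(cos(phi[i]), -sin(phi[i]))
    com <- com + segs$mass[i] * (base + segs$com_offset[i] * u)
    comv <- comv + segs$mass[i] * (basev + segs$com_offset[i] * phid[i] * up)
    base <- base + segs$length[i] * u
    basev <- basev + segs$length[i] * phid[i] * up
    msum <- msum + segs$mass[i]
  }
  list(com = com / msum, com_vel = comv / msum)
}

#' Zero-moment point of the ground reaction
#'
#' Returns the ground-line x coordinate at which the reaction wrench exerts
#' no sagittal moment: `zmp_x = ref_x - feet_moment / F_y`. `feet_moment` is
#' the moment the foot applies to the ground about the point below `ref_x`
#' (the sign convention used by [simulate_sts()] records).
#'
#' @param feet_force 2D ground reaction force (N); `F_y` must be positive
#' @param feet_moment sagittal moment (N m)
#' @param ref_x reference ground x (m)
#' @return x coordinate (m)
#' @export
compute_zmp <- function(feet_force, feet_moment, ref_x) {
  if (feet_force[2] <= 0)
    stop("zero-moment point undefined: vertical feet force must be positive",
         call. = FALSE)
  ref_x - feet_moment / feet_force[2]
}

#' Forward roll-out of the seated model under an open-loop controller
#'
#' Integrates activation and skeletal dynamics with a fixed-step RK4 scheme
#' from the equilibrated sitting posture to the controller's final time.
#' The seat constraint is checked every step and permanently removed the
#' first time its reaction turns non-compressive or violates the friction
#' cone; the release time is recorded. Roll-outs whose joint rates exceed
#' the configured cap are truncated and flagged `failed` (the partial record
#' remains usable by the cost function).
#'
#' @param model `planar_model`
#' @param controller `control_trajectory` (see [decode_controls()])
#' @return object of class `sts_simulation`: time series of states, muscle
#'   forces, seat/feet reactions, COM, ZMP, plus `t_seat_release` and `t_f`
#' @export
simulate_sts <- function(model, controller) {
  stopifnot(inherits(controller, "control_trajectory"))
  out <- cpp_simulate(model$cpp, controller$nodes, controller$t_f,
                      controller$node_dt)
  res <- lapply(out, identity)
  res$seat_engaged <- as.logical(out$seat_engaged)
  res$t_seat_release <- if (is.na(out$t_seat_release)) NA_real_
                        else out$t_seat_release
  res$mg <- model$mass_total * model$gravity
  res$feet_x <- (model$foot$heel_x + model$foot$toe_x) / 2
  res$mu <- model$chair$ground_mu
  res$assist_on <- isTRUE(model$assist$on)
  res$muscle_names <- model$muscles$name
  colnames(res$q) <- colnames(res$qdot) <- colnames(res$qddot) <- JOINTS
  colnames(res$muscle_force) <- model$muscles$name
  class(res) <- "sts_simulation"
  res
}

#' @export
print.sts_simulation <- function(x, ...) {
  cat(sprintf("STS roll-out: %d samples over %.3f s%s\n", length(x$times),
              x$t_f, if (isTRUE(x$failed)) " [diverged]" else ""))
  if (is.na(x$t_seat_release)) {
    cat("  seat never released\n")
  } else {
    cat(sprintf("  seat released at %.3f s\n", x$t_seat_release))
  }
  n <- length(x$times)
  cat(sprintf("  final COM (%.3f, %.3f) m, |qdot|_max %.2f rad/s\n",
              x$com[n, 1], x$com[n, 2], max(abs(x$qdot))))
  invisible(x)
}
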