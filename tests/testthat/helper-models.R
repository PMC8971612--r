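# shared fixtures: all inputs are generated in code

default_model_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_model()
    m
  }
})

# frictionless-joint passive linkage: no muscles, no limit springs, no
# damping, seat constraint off; used by the energy-conservation and
# pendulum oracles
passive_config <- function(qdot_cap = 1000) {
  cfg <- default_model_config()
  cfg$muscles$names <- character(0)
  for (f in c("f_max", "l_opt", "l_slack", "pennation", "v_max",
              "act_tau", "deact_tau"))
    cfg$muscles[[f]] <- numeric(0)
  cfg$muscles$arms <- list()
  cfg$limits$k <- c(0, 0, 0)
  cfg$limits$limit_damping <- c(0, 0, 0)
  cfg$limits$joint_damping <- c(0, 0, 0)
  cfg$chair$engaged <- FALSE
  cfg$integrator$qdot_cap <- qdot_cap
  cfg
}

# minimal synthetic roll-out record for cost-function tests; every series
# is constant unless overridden
synthetic_result <- function(t_f = 1.0, dt = 0.001, model = default_model_cached(),
                             com0 = NULL, comf = NULL,
                             seat_fy = 0, feet_fy = NULL, feet_fx = 0,
                             act = 0, n_act = 8, qdot_f = c(0, 0, 0),
                             zmp_dev = 0, limit = 0, assist = 0,
                             t_seat_release = 0) {
  times <- seq(0, t_f, by = dt)
  n <- length(times)
  mg <- model$mass_total * model$gravity
  if (is.null(feet_fy)) feet_fy <- mg
  cg <- goal_com(model)
  if (is.null(com0)) com0 <- compute_com(model, model$q0)
  if (is.null(comf)) comf <- cg
  com <- matrix(rep(com0, each = n), n, 2)
  com[n, ] <- comf
  feet_x <- (model$foot$heel_x + model$foot$toe_x) / 2
  structure(list(
    times = times,
    q = matrix(0, n, 3, dimnames = list(NULL, JOINTS_T)),
    qdot = rbind(matrix(0, n - 1, 3), qdot_f),
    qddot = matrix(0, n, 3),
    activations = matrix(act, n, n_act),
    muscle_force = matrix(0, n, 8),
    limit_torque = matrix(limit, n, 3),
    seat_force = cbind(0, rep(seat_fy, n)),
    feet_force = cbind(rep(feet_fx, n), rep(feet_fy, n)),
    feet_moment = rep(0, n),
    com = com,
    com_vel = matrix(0, n, 2),
    assist_force = matrix(assist, n, 2),
    zmp_x = rep(feet_x + zmp_dev, n),
    seat_engaged = rep(FALSE, n),
    t_seat_release = t_seat_release,
    t_f = t_f, failed = FALSE,
    mg = mg, feet_x = feet_x, mu = model$chair$ground_mu,
    assist_on = FALSE, muscle_names = model$muscles$name
  ), class = "sts_simulation")
}

JOINTS_T <- c("ankle", "knee", "hip")

# controller helper: per-muscle piecewise-linear profiles on the node grid
controller_from_profiles <- function(layout, profiles, t_f) {
  nodes <- matrix(layout$act_default, layout$n_act, layout$n_nodes)
  tgrid <- seq_len(layout$n_nodes) * layout$node_dt
  for (nm in names(profiles)) {
    i <- match(nm, layout$actuator_names)
    p <- profiles[[nm]]
    nodes[i, ] <- approx(p$t, p$v, xout = tgrid, rule = 2)$y
  }
  control_trajectory(pmin(pmax(nodes, 0), 1), t_f, layout)
}
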