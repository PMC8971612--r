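test_that("build_model reproduces the configured strengths and mass", {
  model <- default_model_cached()
  expect_equal(model$muscles$f_max[model$muscles$name == "VAS"], 9594.0)
  expect_equal(model$mass_total, 75)
  expect_equal(sum(model$segments$mass) + model$foot$mass, 75)
  # uniform strength scaling multiplies every cap
  weak <- build_model(default_model_config(strength_scale = 0.4))
  expect_equal(weak$cpp$mus_fmax, 0.4 * model$muscles$f_max)
})

test_that("build_model rejects invalid anthropometry naming the field", {
  cfg <- default_model_config()
  cfg$segments$thigh$mass <- -1
  expect_error(build_model(cfg), "segments.thigh.mass")
  cfg <- default_model_config()
  cfg$segments$shank$length <- 0
  expect_error(build_model(cfg), "segments.shank.length")
  cfg <- default_model_config()
  cfg$foot$heel_x <- 0.3
  expect_error(build_model(cfg), "heel_x")
  cfg <- default_model_config()
  cfg$strength_scale <- 1.4
  expect_error(build_model(cfg), "strength_scale")
  cfg <- default_model_config()
  cfg$segments$torso$mass <- 40
  expect_error(build_model(cfg), "body_mass")
})

test_that("upright rest with no forces and no gravity is an equilibrium", {
  cfg <- default_model_config()
  cfg$gravity <- 0
  m <- build_model(cfg)
  fd <- forward_dynamics(m, list(q = rep(0, 3), qdot = rep(0, 3)),
                         muscle_forces = rep(0, 8),
                         passive_structures = FALSE)
  expect_equal(fd$qddot, rep(0, 3), tolerance = 1e-12)
})

test_that("single-DOF fall matches the compound-pendulum closed form", {
  # knee and hip locked at zero, no muscles/springs, torso tilt removed:
  # the linkage is a rigid inverted pendulum about the ankle
  cfg <- passive_config()
  cfg$lumbar_lock_angle <- 0
  m <- build_model(cfg)
  segs <- m$segments
  for (theta in c(0.05, 0.2, -0.15)) {
    fd <- forward_dynamics(m, list(q = c(theta, 0, 0), qdot = rep(0, 3)),
                           muscle_forces = NULL,
                           locked = c(FALSE, TRUE, TRUE),
                           passive_structures = FALSE)
    # independent oracle from the configured inertias: distances of segment
    # COMs from the ankle along the (collinear) chain
    d_chain <- cumsum(c(0, segs$length))[1:3] + segs$com_offset
    I_tot <- sum(segs$inertia + segs$mass * d_chain^2)
    qdd_expect <- m$gravity * sum(segs$mass * d_chain) * sin(theta) / I_tot
    expect_equal(fd$qddot[1], qdd_expect, tolerance = 1e-6)
    expect_equal(fd$qddot[2:3], c(0, 0))
  }
})

test_that("static sitting balances seat and feet forces against weight", {
  m <- default_model_cached()
  st <- list(q = m$q0, qdot = rep(0, 3), activations = rep(0.05, 8))
  fd <- forward_dynamics(m, st, seat_engaged = TRUE,
                         locked = c(FALSE, FALSE, TRUE))
  expect_equal(max(abs(fd$qddot)), 0, tolerance = 1e-10)
  mg <- m$mass_total * m$gravity
  expect_equal(fd$seat_reaction[2] + fd$feet_reaction$force[2], mg,
               tolerance = 1e-6 * mg)
  expect_equal(fd$seat_reaction[1] + fd$feet_reaction$force[1], 0,
               tolerance = 1e-6 * mg)
})

test_that("seat release fires on tension or slip, not inside the cone", {
  expect_true(check_seat_release(c(0, -10), 0.8))
  expect_false(check_seat_release(c(10, 100), 0.8))
  expect_true(check_seat_release(c(90, 100), 0.8))
  expect_true(check_seat_release(c(-90, 100), 0.8))
  expect_false(check_seat_release(c(79.9, 100), 0.8))
})

test_that("limit springs are zero inside and restoring outside", {
  m <- default_model_cached()
  expect_equal(limit_spring_torque(m, "knee", 70 * pi / 180), 0)
  expect_lt(limit_spring_torque(m, "knee", 150 * pi / 180), 0)
  expect_gt(limit_spring_torque(m, "knee", -5 * pi / 180), 0)
  # magnitude equals the configured curve at the overshoot
  lim <- m$limits[m$limits$joint == "ankle", ]
  over <- 5 * pi / 180
  expect_equal(limit_spring_torque(m, "ankle", lim$upper + over),
               -lim$k * (exp(lim$rate * over) - 1), tolerance = 1e-12)
  # continuity at the limit
  expect_equal(limit_spring_torque(m, "hip", lim$upper + 1e-12), 0,
               tolerance = 1e-9)
})

test_that("whole-body COM matches a direct mass-weighted sum", {
  m <- default_model_cached()
  com_up <- compute_com(m, rep(0, 3))
  expect_lt(abs(com_up[1] - m$foot$ankle[1]), 0.06)
  expect_true(com_up[2] > 0.8 && com_up[2] < 1.2)
  expect_equal(compute_com_vel(m, m$q0, rep(0, 3)), c(0, 0))
  # agreement between the R chain walk and the compiled kinematics
  q <- c(0.3, 0.9, 1.1)
  expect_equal(compute_com(m, q),
               as.numeric(sitstand:::cpp_com(m$cpp, q)), tolerance = 1e-12)
  qd <- c(-0.4, 1.2, 0.3)
  expect_equal(compute_com_vel(m, q, qd),
               as.numeric(sitstand:::cpp_com_vel(m$cpp, q, qd)),
               tolerance = 1e-12)
})

test_that("degenerate single-segment model puts the COM on that segment", {
  m <- default_model_cached()
  toy <- list(segments = data.frame(name = "rod", mass = 10, length = 1,
                                    com_offset = 0.25, inertia = 0.1,
                                    offset = 0),
              foot = list(mass = 1e-12, ankle = c(0, 0), com = c(0, 0)))
  com <- compute_com(toy, 0.3)
  expect_equal(com, 0.25 * c(sin(0.3), cos(0.3)), tolerance = 1e-9)
})

test_that("zero-moment point follows the moment balance", {
  expect_equal(compute_zmp(c(0, 500), 0, 0.02), 0.02)
  expect_equal(compute_zmp(c(0, 750), 75, 0), -0.1)
  expect_error(compute_zmp(c(10, 0), 5, 0), "undefined")
  # static seated model: ZMP equals the weight line of the
  # foot-borne load, computed by an independent static oracle
  m <- default_model_cached()
  st <- list(q = m$q0, qdot = rep(0, 3), activations = rep(0.05, 8))
  fd <- forward_dynamics(m, st, seat_engaged = TRUE,
                         locked = c(FALSE, FALSE, TRUE))
  zmp <- compute_zmp(fd$feet_reaction$force, fd$feet_reaction$moment,
                     m$foot$ankle[1])
  # oracle: moments about the origin of gravity + seat reaction
  pk <- sitstand:::cpp_point_kinematics(m$cpp, m$q0, rep(0, 3))
  seg_x <- pk$seg_com[1, ]
  seg_moment <- -m$gravity * (sum(m$segments$mass * seg_x) +
                              m$foot$mass * m$foot$com[1])
  lam <- fd$seat_reaction
  hip <- as.numeric(pk$hip)
  seat_moment <- hip[1] * lam[2] - hip[2] * lam[1]
  Ry <- fd$feet_reaction$force[2]
  zmp_oracle <- -(seg_moment + seat_moment) / Ry
  expect_equal(zmp, zmp_oracle, tolerance = 1e-9)
})

test_that("zero-excitation roll-out from sitting never releases the seat", {
  m <- default_model_cached()
  layout <- control_layout(m)
  sim <- simulate_sts(m, decode_controls(sitting_guess(layout), layout))
  expect_true(is.na(sim$t_seat_release))
  expect_true(all(sim$seat_engaged))
  expect_true(all(sim$seat_force[, 2] >= 0))
  expect_false(sim$failed)
})

test_that("passive unconstrained roll-out conserves mechanical energy", {
  m <- build_model(passive_config())
  layout <- control_layout(m)
  traj <- control_trajectory(matrix(0, 0, layout$n_nodes), 1.6, layout)
  sim <- simulate_sts(m, traj)
  expect_false(sim$failed)
  energy <- function(i) {
    M <- sitstand:::cpp_mass_matrix(m$cpp, sim$q[i, ])
    pk <- sitstand:::cpp_point_kinematics(m$cpp, sim$q[i, ], sim$qdot[i, ])
    ke <- 0.5 * drop(t(sim$qdot[i, ]) %*% M %*% sim$qdot[i, ])
    pe <- sum(m$segments$mass * m$gravity * pk$seg_com[2, ])
    ke + pe
  }
  e0 <- energy(1)
  drift <- abs(vapply(seq(1, length(sim$times), by = 100), energy, 0) - e0)
  expect_lt(max(drift), 1e-4 * abs(e0))
})

test_that("degenerate zero-duration roll-out returns a single sample", {
  m <- default_model_cached()
  layout <- control_layout(m)
  traj <- control_trajectory(matrix(0.05, 8, layout$n_nodes), 0, layout)
  sim <- simulate_sts(m, traj)
  expect_equal(length(sim$times), 1L)
  expect_equal(sim$com[1, ], compute_com(m, m$q0), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("seat engagement is monotone and compressive over roll-outs", {
  m <- default_model_cached()
  layout <- control_layout(m)
  set.seed(42)
  for (rep in 1:3) {
    x <- sitting_guess(layout)
    x[seq_len(layout$size - 1)] <-
      pmin(1, pmax(0, x[seq_len(layout$size - 1)] + runif(128, -0.2, 0.6)))
    x[layout$size] <- runif(1, 0.9, 1.6)
    sim <- simulate_sts(m, decode_controls(x, layout))
    eng <- sim$seat_engaged
    expect_true(all(diff(eng) <= 0))  # true...true, false...false
    if (any(eng)) expect_true(all(sim$seat_force[eng, 2] >= -1e-9))
    if (any(!eng)) expect_true(all(sim$seat_force[!eng, ] == 0))
    if (!is.na(sim$t_seat_release))
      expect_equal(sim$t_seat_release, sim$times[which(!eng)[1]])
  }
})

test_that("forward then inverse dynamics recovers the applied torques", {
  m <- default_model_cached()
  set.seed(7)
  for (rep in 1:100) {
    q <- runif(3, c(-0.5, 0, -0.4), c(0.5, 2.0, 1.8))
    qd <- runif(3, -3, 3)
    fmus <- runif(8, 0, 2000)
    assist <- runif(2, -100, 100)
    fd <- forward_dynamics(m, list(q = q, qdot = qd), muscle_forces = fmus,
                           assist_force = assist)
    # expected applied generalized force, assembled independently
    ms <- sitstand:::cpp_muscle_state(m$cpp, q, qd)
    tau_mus <- as.vector(t(ms$arms) %*% fmus)
    tau_spring <- vapply(1:3, function(j)
      limit_spring_torque(m, JOINTS_T[j], q[j]), 0)
    damping <- m$config$limits$joint_damping
    lim_damp <- m$config$limits$limit_damping
    beyond <- q > m$limits$upper | q < m$limits$lower
    tau_applied <- tau_mus + tau_spring - damping * qd -
      ifelse(beyond, lim_damp * qd, 0)
    resid <- inverse_dynamics(m, q, qd, fd$qddot,
                              assist_force = matrix(assist, 1))
    expect_equal(as.numeric(resid), tau_applied,
                 tolerance = 1e-6)
  }
})

test_that("ground reaction balances whole-body momentum (Newton-Euler)", {
  m <- default_model_cached()
  layout <- control_layout(m)
  set.seed(3)
  x <- sitting_guess(layout)
  x[1:128] <- pmin(1, pmax(0, x[1:128] + runif(128, 0, 0.4)))
  x[129] <- 1.2
  sim <- simulate_sts(m, decode_controls(x, layout))
  t <- sim$times
  n <- length(t)
  idx <- seq(10, n - 10, by = 25)
  # skip the release instant: the constraint force is discontinuous there
  if (!is.na(sim$t_seat_release)) {
    i_rel <- which(t >= sim$t_seat_release)[1]
    idx <- idx[abs(idx - i_rel) > 5]
  }
  mg <- m$mass_total * m$gravity
  # independent check: m * dv/dt (central differences of the recorded COM
  # velocity) + weight = feet + seat + assist
  for (i in idx) {
    acc <- m$mass_total *
      (sim$com_vel[i + 1, ] - sim$com_vel[i - 1, ]) / (t[i + 1] - t[i - 1])
    lhs <- acc + c(0, mg)
    rhs <- sim$feet_force[i, ] + sim$seat_force[i, ] + sim$assist_force[i, ]
    expect_lt(max(abs(lhs - rhs)), 5)  # finite-difference acceleration
  }
})

test_that("diverging roll-outs are truncated, flagged, and still scorable", {
  cfg <- passive_config(qdot_cap = 50)
  m <- build_model(cfg)
  layout <- control_layout(m)
  sim <- simulate_sts(m, control_trajectory(matrix(0, 0, layout$n_nodes),
                                            1.6, layout))
  expect_true(sim$failed)
  expect_lt(sim$t_f, 1.6)
  expect_gt(max(abs(sim$qdot)), 50)
  bd <- compute_cost(sim, m)
  expect_true(is.finite(bd$total))
})
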