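test_that("desired accelerations implement the PD lookahead law", {
  tt <- seq(0, 1, by = 0.01)
  ref <- list(times = tt, q = cbind(0.1 * sin(tt), 0.2 * tt, 0.3 * tt^2))
  cfg <- tracking_config(kp = 100, kv = 20, lookahead = 0.01)
  sp <- lapply(1:3, function(j) splinefun(tt, ref$q[, j], method = "natural"))
  q_exp <- vapply(sp, function(f) f(0.5), 0)
  qd_exp <- vapply(sp, function(f) f(0.5, deriv = 1), 0)
  qdd_exp <- vapply(sp, function(f) f(0.51, deriv = 2), 0)
  # zero tracking error: pure feedforward
  a0 <- desired_accelerations(ref, 0.5, q_exp, qd_exp, cfg)
  expect_equal(as.numeric(a0), qdd_exp, tolerance = 1e-10)
  # a pure position error of 0.1 rad with kp = 100 adds 10 rad/s^2
  a1 <- desired_accelerations(ref, 0.5, q_exp - c(0.1, 0, 0), qd_exp, cfg)
  expect_equal(a1[1] - a0[1], 10, tolerance = 1e-10)
  # negating both errors negates the PD correction
  dq <- c(0.05, -0.02, 0.01); dqd <- c(-0.3, 0.1, 0.2)
  ap <- desired_accelerations(ref, 0.5, q_exp + dq, qd_exp + dqd, cfg)
  am <- desired_accelerations(ref, 0.5, q_exp - dq, qd_exp - dqd, cfg)
  expect_equal(as.numeric(ap - a0), -as.numeric(am - a0), tolerance = 1e-10)
  # queries past the reference end hold the last sample and are flagged
  a_end <- desired_accelerations(ref, 1.0, q_exp, qd_exp, cfg)
  expect_true(attr(a_end, "held"))
})

test_that("fast target solves trivial actuator layouts exactly", {
  # one ideal torque actuator per DOF: control = torque / optimal torque
  B <- diag(c(2, 5, 10))
  sol <- fast_target_solve(B, c(1, 1, 1), rep(-Inf, 3), rep(Inf, 3))
  expect_equal(sol$controls, c(0.5, 0.2, 0.1), tolerance = 1e-12)
  # two parallel identical actuators split the load evenly (minimum norm)
  B2 <- matrix(c(1, 1), 1, 2)
  sol2 <- fast_target_solve(B2, 0.8, c(0, 0), c(1, 1))
  expect_equal(sol2$controls, c(0.4, 0.4), tolerance = 1e-12)
  # saturated cheap actuator: the reserve supplies the remainder
  B3 <- matrix(c(10, 1), 1, 2)
  sol3 <- fast_target_solve(B3, 12, c(0, -Inf), c(1, Inf))
  expect_equal(sol3$controls, c(1, 2), tolerance = 1e-10)
})

test_that("fast target matches an independent quadratic-program oracle", {
  library(pracma)
  set.seed(9)
  worst <- 0
  for (rep in 1:100) {
    m <- sample(5:12, 1)
    B <- matrix(rnorm(3 * m), 3, m)
    B[, m - 2:0] <- diag(3) * runif(3, 0.5, 2)  # reserves keep it feasible
    lb <- c(rep(0, m - 3), rep(-50, 3))
    ub <- c(rep(1, m - 3), rep(50, 3))
    target <- rnorm(3, 0, 2)
    sol <- fast_target_solve(B, target, lb, ub)
    qp <- pracma::quadprog(diag(2, m), rep(0, m), Aeq = B, beq = target,
                           lb = lb, ub = ub)
    worst <- max(worst, max(abs(sol$controls - qp$xmin)))
    expect_equal(as.numeric(B %*% qp$xmin), target, tolerance = 1e-6)
  }
  expect_lt(worst, 1e-6)
})

test_that("equality constraints are met exactly when no bound is active", {
  set.seed(10)
  for (rep in 1:20) {
    B <- matrix(rnorm(3 * 8), 3, 8)
    target <- rnorm(3, 0, 0.5)
    sol <- fast_target_solve(B, target, rep(-1e6, 8), rep(1e6, 8))
    expect_equal(sol$achieved, target, tolerance = 1e-8)
  }
})

test_that("self-tracking a simulated motion needs almost no reserves", {
  m <- default_model_cached()
  layout <- control_layout(m)
  sim <- simulate_sts(m, decode_controls(sitting_guess(layout), layout))
  keep <- seq(1, length(sim$times), by = 10)
  reference <- list(times = sim$times[keep], q = sim$q[keep, ])
  external <- list(times = sim$times[keep],
                   seat_force = sim$seat_force[keep, ])
  tr <- track_motion(m, reference, external, tracking_config())
  expect_false(tr$aborted)
  expect_lt(max(abs(tr$peak_reserve)), 1)
  expect_lt(max(abs(tr$tracking_error)), 0.01)
})

test_that("removing a muscle's strength shifts load onto its reserve", {
  cfg <- default_model_config()
  m_full <- build_model(cfg)
  cfg2 <- default_model_config()
  cfg2$muscles$f_max[cfg2$muscles$names == "VAS"] <- 1e-6
  cfg2$muscles$f_max[cfg2$muscles$names == "RF"] <- 1e-6
  m_novas <- build_model(cfg2)
  # a brisk squat-like knee/hip extension from a mild crouch
  tt <- seq(0, 0.8, by = 0.02)
  s <- (1 - cos(pi * tt / 0.8)) / 2
  qref <- cbind(0.15 * (1 - s), 1.0 * (1 - s), 1.0 * (1 - s))
  reference <- list(times = tt, q = qref)
  tr_full <- track_motion(m_full, reference, NULL, tracking_config())
  tr_weak <- track_motion(m_novas, reference, NULL, tracking_config())
  expect_gt(abs(tr_weak$peak_reserve["knee"]),
            abs(tr_full$peak_reserve["knee"]) + 1)
})

test_that("a zero-length window returns an empty result", {
  m <- default_model_cached()
  reference <- list(times = 0, q = matrix(m$q0, 1))
  tr <- track_motion(m, reference, NULL, tracking_config())
  expect_length(tr$times, 0)
  expect_equal(unname(tr$peak_reserve), c(0, 0, 0))
})

test_that("the diagnosis names the joint whose reserves persist", {
  stub <- function(peaks) structure(list(peak_reserve =
    setNames(peaks, c("ankle", "knee", "hip"))), class = "tracking_result")
  # hip-favoured setup shows a large knee reserve; knee-favoured setup shows
  # a smaller hip reserve: the knee extensors are implicated
  d <- diagnose_failure(stub(c(0.2, -19.81, -1.5)),
                        stub(c(0.3, -25.0, -12.05)))
  expect_identical(d$implicated, "knee")
  # no reserves anywhere: nothing implicated
  d0 <- diagnose_failure(stub(c(0, 0, 0)), stub(c(0, 0, 0)))
  expect_true(is.na(d0$implicated))
  # symmetric persistence: tie, no joint named
  dt <- diagnose_failure(stub(c(0, 10, 10)), stub(c(0, 10, 10)))
  expect_true(is.na(dt$implicated))
})
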