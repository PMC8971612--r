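test_that("goal COM is the upright posture COM, independent of the chair", {
  m <- default_model_cached()
  expect_equal(goal_com(m), compute_com(m, rep(0, 3)))
  cfg <- default_model_config()
  cfg$chair$seat_point <- c(-0.5, 0.7)
  m2 <- build_model(cfg)
  expect_equal(goal_com(m2), goal_com(m))
})

test_that("alpha hits its endpoints and clamps regression", {
  c0 <- c(-0.15, 0.74); cg <- c(0.03, 0.98)
  expect_equal(compute_alpha(c0, c0, cg), 0)
  expect_equal(compute_alpha(cg, c0, cg), 1)
  # final COM farther from the goal than the start: clamped at 0
  expect_equal(compute_alpha(c(-1, 0), c0, cg), 0)
  expect_error(compute_alpha(c0, cg, cg), "undefined")
})

test_that("exponential chair weight integrates to one", {
  for (t_f in c(0.3, 0.8, 1.1, 1.6)) {
    tau <- 1.6 / 8
    w <- function(t) exp(t / tau) / (tau * (exp(t_f / tau) - 1))
    val <- stats::integrate(w, 0, t_f, rel.tol = 1e-12)$value
    expect_equal(val, 1, tolerance = 1e-9)
  }
})

test_that("a stationary-at-goal roll-out zeroes every cost term", {
  m <- default_model_cached()
  res <- synthetic_result(model = m)  # cf = goal, everything else quiescent
  bd <- compute_cost(res, m)
  expect_equal(bd$alpha, 1)
  expect_equal(unname(bd$phi), rep(0, 10), tolerance = 1e-9)
  expect_equal(bd$total, 0, tolerance = 1e-6)
})

test_that("constant chair force passes through the normalized weight", {
  m <- default_model_cached()
  c0 <- compute_com(m, m$q0)
  res <- synthetic_result(model = m, comf = c0, seat_fy = 137)
  bd <- compute_cost(res, m)
  expect_equal(bd$alpha, 0)
  expect_equal(unname(bd$phi["phi2"]), 137, tolerance = 1e-4 * 137)
})

test_that("constant activations integrate to a^2 t_f per actuator", {
  m <- default_model_cached()
  res <- synthetic_result(model = m, comf = compute_com(m, m$q0),
                          act = 0.3, t_f = 1.2)
  bd <- compute_cost(res, m)
  expect_equal(unname(bd$phi["phi3"]), 0.3^2 * 1.2, tolerance = 1e-9)
  expect_equal(unname(bd$phi["phi4"]), 0, tolerance = 1e-9)
})

test_that("progress gating scales terms 7-10 and mutes term 2", {
  m <- default_model_cached()
  mg <- m$mass_total * m$gravity
  c0 <- compute_com(m, m$q0)
  cg <- goal_com(m)
  # same kinetics, two levels of completion
  mk <- function(comf) synthetic_result(model = m, comf = comf,
                                        feet_fx = 0.9 * mg, zmp_dev = 0.2,
                                        qdot_f = c(1, 1, 1), seat_fy = 100)
  res0 <- mk(c0)                     # alpha = 0
  res_half <- mk(c0 + 0.5 * (cg - c0))
  res_full <- mk(cg)                 # alpha = 1
  bd0 <- compute_cost(res0, m)
  bdh <- compute_cost(res_half, m)
  bd1 <- compute_cost(res_full, m)
  expect_equal(bd0$alpha, 0)
  expect_equal(bd1$alpha, 1)
  gated <- paste0("phi", 7:10)
  expect_equal(unname(bd0$phi[gated]), rep(0, 4))
  # linear alpha scaling with the kinetics held fixed
  expect_equal(unname(bdh$phi[gated]) / bdh$alpha,
               unname(bd1$phi[gated]), tolerance = 1e-9)
  # chair term vanishes as alpha reaches one
  expect_gt(bd0$phi["phi2"], 0)
  expect_equal(unname(bd1$phi["phi2"]), 0)
})

test_that("slip penalty is the worst friction-cone violation and monotone", {
  m <- default_model_cached()
  mg <- m$mass_total * m$gravity
  cg <- goal_com(m)
  res <- synthetic_result(model = m, comf = cg, feet_fx = 0)
  res$feet_force[, 1] <- 0
  res$feet_force[300, 1] <- m$chair$ground_mu * mg + 50
  bd <- compute_cost(res, m)
  expect_equal(unname(bd$phi["phi7"]), 50, tolerance = 1e-9)
  # adding a second, smaller violation cannot decrease the penalty
  res2 <- res
  res2$feet_force[500, 1] <- m$chair$ground_mu * mg + 20
  bd2 <- compute_cost(res2, m)
  expect_gte(bd2$phi["phi7"], bd$phi["phi7"])
})

test_that("feet-force deviation window starts at seat release", {
  m <- default_model_cached()
  mg <- m$mass_total * m$gravity
  res <- synthetic_result(model = m, comf = goal_com(m), t_f = 1.0,
                          t_seat_release = 0.5)
  res$feet_force[, 2] <- mg
  res$feet_force[200, 2] <- mg + 400  # before release: ignored
  res$feet_force[700, 2] <- mg + 100  # inside the window
  bd <- compute_cost(res, m)
  expect_equal(unname(bd$phi["phi10"]), 100, tolerance = 1e-9)
})

test_that("quadrature agrees between the native and a 10x finer grid", {
  m <- default_model_cached()
  mk <- function(dt) {
    res <- synthetic_result(model = m, t_f = 1.0, dt = dt,
                            comf = goal_com(m), t_seat_release = 0.2)
    t <- res$times
    n <- length(t)
    res$activations <- matrix(rep(0.3 + 0.2 * sin(pi * t), 8), n, 8)
    res$seat_force[, 2] <- 80 * exp(-3 * t)
    res$limit_torque[, 2] <- 0.5 * (sin(4 * t) + 1.2)
    res$com[n, ] <- res$com[1, ] + 0.5 * (goal_com(m) - res$com[1, ])
    res
  }
  phi_a <- compute_cost(mk(0.001), m)$phi
  phi_b <- compute_cost(mk(0.0001), m)$phi
  on <- phi_b > 1e-8
  expect_true(all(abs(phi_a[on] - phi_b[on]) / phi_b[on] < 1e-5))
})

test_that("the weighted total applies the configured weights", {
  w <- default_cost_weights()
  expect_equal(w$w, c(800, 1.2, 175, 70, 5, 10, 0.1, 1000, 6, 0.3))
  expect_equal(w$tau, 0.2)
  bd <- structure(list(alpha = 1, phi = setNames(rep(0, 10),
                                                 paste0("phi", 1:10))),
                  class = "cost_breakdown")
  expect_equal(total_cost(bd, w), 0)
  bd$phi["phi1"] <- 1
  expect_equal(total_cost(bd, w), 800)
  bd$phi["phi1"] <- 0
  bd$phi["phi8"] <- 0.01
  expect_equal(total_cost(bd, w), 10)
})
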