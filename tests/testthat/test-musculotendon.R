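test_that("activation dynamics follow the two-time-constant first-order law", {
  expect_equal(activation_derivative(0.5, 0.5), 0)
  expect_equal(activation_derivative(1, 0, act_tau = 0.01), 100)
  expect_equal(activation_derivative(0, 1, deact_tau = 0.04), -25)
  expect_error(activation_derivative(1.5, 0))
})

test_that("Hill curves satisfy their normalization and endpoints", {
  expect_equal(active_force_length(1), 1)
  expect_equal(force_velocity(0), 1)
  expect_equal(force_velocity(-1), 0)
  expect_equal(force_velocity(-2), 0)
  expect_equal(passive_force_length(0.9), 0)
  expect_equal(passive_force_length(1.0), 0)
  # passive toe strictly increasing beyond slack
  l <- seq(1.01, 1.6, by = 0.05)
  expect_true(all(diff(passive_force_length(l)) > 0))
  # eccentric branch exceeds 1 but stays below the plateau
  v <- seq(0.01, 5, by = 0.1)
  fv <- force_velocity(v)
  expect_true(all(fv > 1 & fv < 1.4))
  # C1 continuity at zero velocity
  h <- 1e-7
  expect_equal((force_velocity(h) - force_velocity(-h)) / (2 * h),
               1 + 1 / 0.25, tolerance = 1e-4)
})

test_that("isometric force at optimal length equals maximum strength", {
  m <- default_model_cached()
  f <- compute_muscle_force(m, "VAS", activation = 1, l_norm = 1, v_norm = 0)
  expect_equal(f$tendon, 9594.0)
  f0 <- compute_muscle_force(m, "GMAX", activation = 0, l_norm = 1)
  expect_equal(f0$tendon, 0)
  fsol <- compute_muscle_force(m, "SOL", activation = 0, l_norm = 1.3)
  expect_gt(fsol$tendon, 0)
  expect_equal(fsol$active, 0)
})

test_that("halving the strength scale halves the tendon force", {
  m1 <- default_model_cached()
  m2 <- build_model(default_model_config(strength_scale = 0.5))
  for (mus in c("VAS", "HAMS", "TA")) {
    f1 <- compute_muscle_force(m1, mus, 0.7, 1.15, -0.2)
    f2 <- compute_muscle_force(m2, mus, 0.7, 1.15, -0.2)
    expect_equal(f2$tendon, f1$tendon / 2, tolerance = 1e-12)
  }
})

test_that("rigid-tendon equilibration is the kinematic identity", {
  m <- default_model_cached()
  eq <- equilibrate_muscles(m, m$q0, activation = 0.05)
  for (i in seq_len(nrow(m$muscles))) {
    p <- muscle_path(m, i, m$q0)
    expect_equal(eq$fiber_length[i],
                 (p$length - m$muscles$l_slack[i]) /
                   cos(m$muscles$pennation[i]), tolerance = 1e-12)
  }
})

test_that("elastic-tendon equilibration matches a bisection oracle", {
  m <- default_model_cached()
  eq <- equilibrate_muscles(m, m$q0, activation = 0.05,
                            elastic_tendon = TRUE)
  cfg <- m$config$curves
  for (i in c(2, 5, 7)) {   # GMAX, VAS, SOL: stretched at sitting
    mus <- m$muscles[i, ]
    p <- muscle_path(m, i, m$q0)$length
    resid <- function(lf) {
      ln <- lf / mus$l_opt
      fib <- mus$f_max * (0.05 * sitstand:::cpp_curve_fl(ln, cfg$fl_width) +
                          sitstand:::cpp_curve_fp(ln, cfg$fp_kpe, cfg$fp_e0))
      eps <- (p - lf - mus$l_slack) / mus$l_slack
      ten <- if (eps <= 0) 0 else mus$f_max * eps / 0.033
      fib - ten
    }
    # plain bisection, independent of the package root finder
    lo <- 0.01 * mus$l_opt; hi <- 2 * mus$l_opt
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (resid(lo) * resid(mid) <= 0) hi <- mid else lo <- mid
    }
    ln <- ((lo + hi) / 2) / mus$l_opt
    f_expect <- mus$f_max * (0.05 * sitstand:::cpp_curve_fl(ln, cfg$fl_width) +
                             sitstand:::cpp_curve_fp(ln, cfg$fp_kpe, cfg$fp_e0))
    expect_equal(eq$tendon_force[i], f_expect, tolerance = 1e-9)
  }
})

test_that("moment arms evaluate the configured model with correct signs", {
  m <- default_model_cached()
  # constant arms are angle-independent
  expect_equal(moment_arm(m, "VAS", c(0, 0.3, 0), "knee"),
               moment_arm(m, "VAS", c(0, 2.0, 0), "knee"))
  # biarticular hamstrings: extension at the hip, flexion at the knee,
  # opposite knee sign to the vasti
  q <- c(0.1, 1.0, 1.0)
  expect_lt(moment_arm(m, "HAMS", q, "hip"), 0)
  expect_gt(moment_arm(m, "HAMS", q, "knee"), 0)
  expect_lt(moment_arm(m, "VAS", q, "knee"), 0)
  expect_error(moment_arm(m, "VAS", q, "hip"), "does not span")
})

test_that("polynomial moment arms match direct evaluation and quadrature", {
  cfg <- default_model_config()
  co <- c(0.03, 0.01, -0.004, 0.002)
  cfg$muscles$arms$VAS <- list(knee = -co)
  m <- build_model(cfg)
  q <- c(0, 0.5, 0)
  horner <- -(co[1] + co[2] * 0.5 + co[3] * 0.25 + co[4] * 0.125)
  expect_equal(moment_arm(m, "VAS", q, "knee"), horner, tolerance = 1e-12)
  # path change equals the quadrature of the arm over the joint sweep
  qa <- c(0, 0.2, 0); qb <- c(0, 1.4, 0)
  dL <- muscle_path(m, "VAS", qb)$length - muscle_path(m, "VAS", qa)$length
  arm_fun <- function(x) -(co[1] + co[2] * x + co[3] * x^2 + co[4] * x^3)
  quad <- stats::integrate(arm_fun, 0.2, 1.4, rel.tol = 1e-12)$value
  expect_equal(dL, -quad, tolerance = 1e-8)
})

test_that("path length and moment arms are mutually consistent", {
  m <- default_model_cached()
  set.seed(5)
  h <- 1e-6
  for (rep in 1:50) {
    q <- runif(3, c(-0.5, 0, -0.4), c(0.5, 2.2, 1.9))
    ms <- sitstand:::cpp_muscle_state(m$cpp, q, rep(0, 3))
    for (j in 1:3) {
      qp <- q; qp[j] <- q[j] + h
      qm <- q; qm[j] <- q[j] - h
      dl <- (sitstand:::cpp_muscle_state(m$cpp, qp, rep(0, 3))$path_len -
             sitstand:::cpp_muscle_state(m$cpp, qm, rep(0, 3))$path_len) /
            (2 * h)
      expect_true(all(abs(dl + ms$arms[, j]) < 1e-6))
    }
  }
})

test_that("path velocity is the Jacobian times the joint rates", {
  m <- default_model_cached()
  expect_equal(muscle_path(m, "HAMS", c(0.1, 0.8, 0.9), rep(0, 3))$velocity, 0)
  qd <- c(0.5, -1.2, 2.0)
  q <- c(0.1, 0.8, 0.9)
  ms <- sitstand:::cpp_muscle_state(m$cpp, q, qd)
  expect_equal(ms$path_vel, as.vector(-ms$arms %*% qd), tolerance = 1e-12)
  # constant arm: delta L = -r * delta q
  r <- moment_arm(m, "VAS", q, "knee")
  dq <- 0.4
  q2 <- q + c(0, dq, 0)
  dL <- muscle_path(m, "VAS", q2)$length - muscle_path(m, "VAS", q)$length
  expect_equal(dL, -r * dq, tolerance = 1e-12)
})

test_that("activations stay within bounds under extreme excitations", {
  m <- default_model_cached()
  layout <- control_layout(m)
  nodes <- matrix(rep(c(0, 1), length.out = 8 * 16), 8, 16)
  sim <- simulate_sts(m, control_trajectory(nodes, 1.2, layout))
  expect_true(all(sim$activations >= 0 & sim$activations <= 1))
  # active component bounded by the eccentric plateau times the strength cap
  fecc <- m$config$curves$fv_fecc
  caps <- matrix(m$muscles$f_max, nrow(sim$muscle_force), 8, byrow = TRUE)
  expect_true(all(sim$muscle_active_force >= -1e-9))
  expect_true(all(sim$muscle_active_force - caps * fecc < 1e-9))
})
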