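#' Tracking configuration
#'
#' Gains and discretization of the computed-muscle-control style tracker.
#' Defaults pair `kp = 100` 1/s^2 with `kv = 20` 1/s (critically damped) and
#' look ahead `0.01` s. `reserve_optimal_torque` sets the torque each ideal
#' reserve actuator produces per unit control at the ankle, knee and hip;
#' small values make reserve use expensive so reserves engage only when the
#' muscles saturate.
#'
#' @param kp,kv PD feedback gains (per DOF or scalar)
#' @param lookahead time horizon T (s) of the desired-acceleration law
#' @param step tracking step (s)
#' @param reserve_optimal_torque per-DOF N m per unit control
#' @param reserve_bound symmetric bound on reserve controls (default
#'   unbounded, so the equality constraints always stay feasible)
#' @param abort_error tracking-error threshold (rad) that aborts the run
#' @return list of class `tracking_config`
#' @export
tracking_config <- function(kp = 100, kv = 20, lookahead = 0.01, step = 0.01,
                            reserve_optimal_torque = c(1, 1, 1),
                            reserve_bound = Inf, abort_error = 1.0) {
  stopifnot(all(kp > 0), all(kv > 0), lookahead > 0, step > 0,
            all(reserve_optimal_torque > 0))
  structure(list(kp = rep(kp, length.out = 3), kv = rep(kv, length.out = 3),
                 lookahead = lookahead, step = step,
                 reserve_optimal_torque = rep(reserve_optimal_torque,
                                              length.out = 3),
                 reserve_bound = reserve_bound, abort_error = abort_error),
            class = "tracking_config")
}

# spline interpolators (value, velocity, acceleration) for a reference
# trajectory given as times + n x 3 joint-angle matrix
reference_splines <- function(times, q) {
  q <- rbind2mat(q)
  lapply(1:3, function(j) splinefun(times, q[, j], method = "natural"))
}

#' PD desired accelerations
#'
#' `qddot* (t+T) = qddot_exp(t+T) + kv (qdot_exp(t) - qdot(t))
#'  + kp (q_exp(t) - q(t))`. Queries past the end of the reference hold the
#' last reference sample (flagged via attribute `held`).
#'
#' @param reference list with `times` and `q` (n x 3, rad)
#' @param t current time (s)
#' @param q,qdot current joint angles (rad) and rates (rad/s)
#' @param config `tracking_config`
#' @return desired accelerations (rad/s^2, length 3)
#' @export
desired_accelerations <- function(reference, t, q, qdot,
                                  config = tracking_config()) {
  sp <- reference_splines(reference$times, reference$q)
  t_end <- max(reference$times)
  ta <- min(t + config$lookahead, t_end)
  te <- min(t, t_end)
  qddot_exp <- vapply(sp, function(f) f(ta, deriv = 2), 0)
  qdot_exp <- vapply(sp, function(f) f(te, deriv = 1), 0)
  q_exp <- vapply(sp, function(f) f(te), 0)
  out <- qddot_exp + config$kv * (qdot_exp - qdot) + config$kp * (q_exp - q)
  attr(out, "held") <- (t + config$lookahead) > t_end
  out
}

#' Fast-target static optimization
#'
#' Minimizes the sum of squared controls subject to the achieved generalized
#' accelerations equalling their targets: `min sum(e_i^2)` s.t. `B e = target`
#' and `lower <= e <= upper`. Solved exactly by a KKT/active-set iteration on
#' the bound constraints.
#'
#' @param B 3 x m matrix of acceleration per unit control
#' @param target desired acceleration change (length 3)
#' @param lower,upper control bounds (length m)
#' @return list with `controls`, `achieved` accelerations, `active` bound
#'   flags and iteration count
#' @export
fast_target_solve <- function(B, target, lower, upper) {
  m <- ncol(B)
  stopifnot(length(lower) == m, length(upper) == m)
  active <- integer(m)         # 0 free, +1 at upper, -1 at lower
  e <- numeric(m)
  for (iter in 1:(3 * m + 10)) {
    free <- which(active == 0L)
    fixed <- which(active != 0L)
    e[fixed] <- ifelse(active[fixed] > 0, upper[fixed], lower[fixed])
    r <- target
    if (length(fixed))
      r <- r - as.vector(B[, fixed, drop = FALSE] %*% e[fixed])
    if (length(free)) {
      Bf <- B[, free, drop = FALSE]
      G <- Bf %*% t(Bf)
      w <- solve(G + 1e-12 * diag(nrow(G)), r)
      e[free] <- as.vector(crossprod(Bf, w))
    } else {
      w <- rep(0, nrow(B))
    }
    viol_up <- free[e[free] > upper[free] + 1e-10]
    viol_lo <- free[e[free] < lower[free] - 1e-10]
    if (length(viol_up) || length(viol_lo)) {
      active[viol_up] <- 1L
      active[viol_lo] <- -1L
      next
    }
    if (length(fixed)) {
      g <- as.vector(crossprod(B[, fixed, drop = FALSE], w))
      rel_up <- fixed[active[fixed] > 0 & g < upper[fixed] - 1e-10]
      rel_lo <- fixed[active[fixed] < 0 & g > lower[fixed] + 1e-10]
      rel <- c(rel_up, rel_lo)
      if (length(rel)) {
        # release one constraint at a time to avoid cycling
        worst <- rel[which.max(abs(g[match(rel, fixed)] - e[rel]))]
        active[worst] <- 0L
        next
      }
    }
    break
  }
  list(controls = e, achieved = as.vector(B %*% e),
       active = active, iterations = iter)
}

# linear interpolation of an external force series (n x 2) at time t
interp_force <- function(times, F, t) {
  if (is.null(F)) return(c(0, 0))
  F <- rbind2mat(F, 2)
  c(approx(times, F[, 1], t, rule = 2)$y, approx(times, F[, 2], t, rule = 2)$y)
}

#' Track a reference kinematic trajectory
#'
#' Steps through the reference window: at each step the PD law gives desired
#' accelerations, the fast target distributes them over muscles (bounded
#' controls scaling the instantaneous maximum active force; passive fiber
#' forces act as an always-present baseline) and ideal reserve actuators,
#' and the skeletal dynamics are advanced one step with the solved controls.
#' Recorded seat-constraint and assistance forces are supplied as external
#' forces (the tracker runs without the seat constraint).
#'
#' @param model `planar_model`
#' @param reference list with `times` and `q` (n x 3 joint angles, rad)
#' @param external optional list with `times`, `seat_force` (n x 2) and
#'   `assist_force` (n x 2) applied at the femur head / torso COM
#' @param config `tracking_config`
#' @return object of class `tracking_result`: per-step controls, reserve
#'   torques, tracking errors, and signed peak reserve torque per DOF
#' @export
track_motion <- function(model, reference, external = NULL,
                         config = tracking_config()) {
  times_ref <- reference$times
  qref <- rbind2mat(reference$q)
  n_mus <- nrow(model$muscles)
  res_opt <- config$reserve_optimal_torque
  t0 <- times_ref[1]
  t_end <- max(times_ref)
  steps <- seq(t0, t_end, by = config$step)
  nm <- c(model$muscles$name, paste0("reserve_", JOINTS))

  if (length(steps) < 2 || t_end - t0 < config$step) {
    return(structure(list(times = numeric(0),
                          controls = matrix(0, 0, n_mus + 3,
                                            dimnames = list(NULL, nm)),
                          reserve_torque = matrix(0, 0, 3),
                          tracking_error = matrix(0, 0, 3),
                          q = matrix(0, 0, 3),
                          peak_reserve = setNames(rep(0, 3), JOINTS),
                          reserve_optimal_torque = res_opt,
                          aborted = FALSE, config = config),
                     class = "tracking_result"))
  }

  sp <- reference_splines(times_ref, qref)
  q <- vapply(sp, function(f) f(t0), 0)
  qd <- vapply(sp, function(f) f(t0, deriv = 1), 0)

  n_rec <- length(steps)
  CTRL <- matrix(NA_real_, n_rec, n_mus + 3, dimnames = list(NULL, nm))
  RES <- matrix(NA_real_, n_rec, 3, dimnames = list(NULL, JOINTS))
  ERR <- matrix(NA_real_, n_rec, 3, dimnames = list(NULL, JOINTS))
  QT <- matrix(NA_real_, n_rec, 3, dimnames = list(NULL, JOINTS))
  aborted <- FALSE
  last <- 0

  for (i in seq_along(steps)) {
    t <- steps[i]
    q_exp <- vapply(sp, function(f) f(min(t, t_end)), 0)
    err <- q_exp - q
    if (max(abs(err)) > config$abort_error) { aborted <- TRUE; break }

    qdd_star <- desired_accelerations(reference, t, q, qd, config)

    ms <- cpp_muscle_state(model$cpp, q, qd)
    fl <- vapply(ms$l_norm, cpp_curve_fl, 0,
                 width = model$config$curves$fl_width)
    fv <- vapply(ms$v_norm, cpp_curve_fv, 0, af = model$config$curves$fv_af,
                 fecc = model$config$curves$fv_fecc)
    fp <- vapply(ms$l_norm, cpp_curve_fp, 0, kpe = model$config$curves$fp_kpe,
                 e0 = model$config$curves$fp_e0)
    fmax_sc <- model$muscles$f_max * model$strength_scale
    cap <- fmax_sc * fl * fv * cos(model$muscles$pennation)
    passive <- fmax_sc * fp

    seat_f <- interp_force(external$times, external$seat_force, t)
    assist_f <- interp_force(external$times, external$assist_force, t)

    base <- cpp_forward_dynamics(model$cpp, q, qd, passive, NULL,
                                 assist_f, seat_f, c(0, 0, 0),
                                 FALSE, c(0L, 0L, 0L), TRUE)
    Minv <- solve(cpp_mass_matrix(model$cpp, q))
    Tau <- cbind(t(ms$arms * cap), diag(res_opt))
    B <- Minv %*% Tau
    sol <- fast_target_solve(B, qdd_star - as.numeric(base$qdd),
                             lower = c(rep(0, n_mus),
                                       rep(-config$reserve_bound, 3)),
                             upper = c(rep(1, n_mus),
                                       rep(config$reserve_bound, 3)))
    e <- sol$controls
    CTRL[i, ] <- e
    RES[i, ] <- res_opt * e[n_mus + 1:3]
    ERR[i, ] <- err
    QT[i, ] <- q
    last <- i
    if (i == n_rec) break

    # advance one step with frozen actuator forces
    tendon <- passive + cap * e[1:n_mus]
    res_tau <- res_opt * e[n_mus + 1:3]
    h <- steps[i + 1] - t
    deriv <- function(qq, qqd) {
      as.numeric(cpp_forward_dynamics(model$cpp, qq, qqd, tendon, NULL,
                                      assist_f, seat_f, res_tau, FALSE,
                                      c(0L, 0L, 0L), TRUE)$qdd)
    }
    k1v <- deriv(q, qd)
    k2q <- qd + h / 2 * k1v; k2v <- deriv(q + h / 2 * qd, k2q)
    k3q <- qd + h / 2 * k2v
    k3v <- deriv(q + h / 2 * (qd + h / 2 * k1v), k3q)
    k4q <- qd + h * k3v
    k4v <- deriv(q + h * (qd + h / 2 * k2v), k4q)
    q <- q + h / 6 * (qd + 2 * k2q + 2 * k3q + k4q)
    qd <- qd + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
  }

  keep <- seq_len(last)
  peak <- vapply(1:3, function(j) {
    x <- RES[keep, j]
    if (!length(x)) return(0)
    x[which.max(abs(x))]
  }, 0)
  structure(list(times = steps[keep], controls = CTRL[keep, , drop = FALSE],
                 reserve_torque = RES[keep, , drop = FALSE],
                 tracking_error = ERR[keep, , drop = FALSE],
                 q = QT[keep, , drop = FALSE],
                 peak_reserve = setNames(peak, JOINTS),
                 reserve_optimal_torque = setNames(res_opt, JOINTS),
                 aborted = aborted, config = config),
            class = "tracking_result")
}

#' @export
print.tracking_result <- function(x, ...) {
  cat(sprintf("tracking result: %d steps%s\n", length(x$times),
              if (isTRUE(x$aborted)) " [aborted]" else ""))
  cat("  peak reserve torques (N m):\n")
  print(round(x$peak_reserve, 3))
  invisible(x)
}

#' Diagnose the joint-level cause of a tracking failure
#'
#' Compares two tracked setups of the same reference with complementary
#' reserve pricing (e.g., hip reserve cheap in one, knee reserve cheap in the
#' other). A joint is implicated when its reserve torque persists in both
#' setups - including the setup where that reserve is expensive - which
#' flags the muscle group at that joint as too weak for the reference motion.
#' The persistence score per joint is the smaller of its two peak reserve
#' magnitudes.
#'
#' @param setup1,setup2 `tracking_result` objects from the same reference
#' @param threshold minimum persistent reserve torque (N m) to implicate
#' @return list of class `sts_diagnosis` with per-setup peaks, persistence
#'   scores and the implicated joint (`NA` if none, or on a tie)
#' @export
diagnose_failure <- function(setup1, setup2, threshold = 1.0) {
  p1 <- abs(setup1$peak_reserve)
  p2 <- abs(setup2$peak_reserve)
  score <- pmin(p1, p2)
  implicated <- NA_character_
  if (max(score) > threshold) {
    top <- which(score == max(score))
    if (length(top) == 1) implicated <- JOINTS[top]
  }
  structure(list(peaks_setup1 = setup1$peak_reserve,
                 peaks_setup2 = setup2$peak_reserve,
                 persistence = score, implicated = implicated),
            class = "sts_diagnosis")
}

#' @export
print.sts_diagnosis <- function(x, ...) {
  cat("reserve-actuator weakness diagnosis\n")
  m <- rbind(setup1 = x$peaks_setup1, setup2 = x$peaks_setup2,
             persistence = x$persistence)
  print(round(m, 3))
  cat(if (is.na(x$implicated)) "  no joint implicated\n"
      else sprintf("  implicated joint: %s\n", x$implicated))
  invisible(x)
}
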