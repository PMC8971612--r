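#' Cost-function weights
#'
#' Default weights of the ten-term roll-out cost and the time constant of the
#' exponential chair-contact weighting (`tau = t_max / 8`).
#'
#' @param t_max horizon (s)
#' @return list with `w` (length 10) and `tau`
#' @export
default_cost_weights <- function(t_max = 1.6) {
  list(w = c(800, 1.2, 175, 70, 5, 10, 0.1, 1000, 6, 0.3), tau = t_max / 8)
}

#' Goal centre-of-mass position (standing upright)
#' @param model `planar_model`
#' @return 2D position (m)
#' @export
goal_com <- function(model) {
  compute_com(model, rep(0, nrow(model$segments)))
}

#' Sit-to-stand progress scalar
#'
#' `alpha = 1 - min(d(cf, goal), d(c0, goal)) / d(c0, goal)`: 0 when the final
#' COM is no closer to the standing COM than the initial COM, 1 when it
#' reaches the goal.
#'
#' @param cf,c0,c_goal 2D COM positions at `t_f`, at `t_0`, and standing
#' @return value in \[0, 1\]
#' @export
compute_alpha <- function(cf, c0, c_goal) {
  d0 <- sqrt(sum((c0 - c_goal)^2))
  if (d0 <= 0)
    stop("alpha undefined: initial COM coincides with the goal COM",
         call. = FALSE)
  df <- sqrt(sum((cf - c_goal)^2))
  1 - min(df, d0) / d0
}

trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(t)) / 2
}

# central-difference derivative on a (possibly non-uniform) grid
time_deriv <- function(t, y) {
  n <- length(t)
  if (n < 2) return(rep(0, n))
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d
}

#' Evaluate the ten-term roll-out cost
#'
#' Computes the progress scalar `alpha` and the ten cost terms on a recorded
#' roll-out: (1) the ratio of final to initial COM distance from the standing
#' goal; (2) the exponentially time-weighted seat-force integral, gated by
#' `1 - alpha` (the weight integrates to one over the roll-out); (3, 4) the
#' mean squared activation and activation-rate integrals over actuators;
#' (5) the assistance-force magnitude integral; (6) the absolute limit-spring
#' torque integral summed over joints; (7) the worst slip-condition violation
#' of the ground reaction; (8) the largest zero-moment-point excursion from
#' the foot midpoint; (9) the terminal joint speeds; and (10) the deviation
#' of vertical ground force extrema (after seat release) and terminal value
#' from body weight. Terms 7-10 are scaled by `alpha` so that unstable early
#' candidates are not over-penalized.
#'
#' @param result `sts_simulation`
#' @param model `planar_model`
#' @param weights see [default_cost_weights()]
#' @param zmp_term `"max"` (default) uses the worst-case ZMP excursion in
#'   term 8; `"integral"` uses the time integral of the excursion instead
#' @return object of class `cost_breakdown` with `alpha`, `phi` (length 10),
#'   `total`, and the COM anchor points
#' @export
compute_cost <- function(result, model, weights = default_cost_weights(),
                         zmp_term = c("max", "integral")) {
  zmp_term <- match.arg(zmp_term)
  t <- result$times
  n <- length(t)
  t_f <- t[n]
  c0 <- result$com[1, ]
  cf <- result$com[n, ]
  cg <- goal_com(model)
  alpha <- compute_alpha(cf, c0, cg)
  mg <- result$mg
  tau <- weights$tau

  phi <- numeric(10)
  phi[1] <- sqrt(sum((cf - cg)^2)) / sqrt(sum((c0 - cg)^2))

  if (t_f > 0) {
    wexp <- exp(t / tau) / (tau * (exp(t_f / tau) - 1))
    phi[2] <- (1 - alpha) * trapz(t, wexp * result$seat_force[, 2])
  }

  act <- result$activations
  # trapezoid weights on the stored grid, applied column-wise
  tw <- numeric(n)
  if (n > 1) {
    dtv <- diff(t)
    tw[1] <- dtv[1] / 2
    tw[n] <- dtv[n - 1] / 2
    if (n > 2) tw[2:(n - 1)] <- (dtv[-1] + dtv[-(n - 1)]) / 2
  }
  if (ncol(act) > 0) phi[3] <- mean(colSums(act^2 * tw))
  if (n > 2 && ncol(act) > 0) {
    adot <- act
    adot[2:(n - 1), ] <- (act[3:n, , drop = FALSE] -
                          act[1:(n - 2), , drop = FALSE]) /
                         (t[3:n] - t[1:(n - 2)])
    adot[1, ] <- (act[2, ] - act[1, ]) / (t[2] - t[1])
    adot[n, ] <- (act[n, ] - act[n - 1, ]) / (t[n] - t[n - 1])
    phi[4] <- mean(colSums(adot^2 * tw))
  }

  phi[5] <- sum(sqrt(rowSums(result$assist_force^2)) * tw)

  phi[6] <- sum(colSums(abs(result$limit_torque) * tw))

  slip <- pmax(0, abs(result$feet_force[, 1]) -
                    result$mu * result$feet_force[, 2])
  phi[7] <- alpha * max(slip)

  dev <- abs(result$zmp_x - result$feet_x)
  ok <- is.finite(dev)
  if (any(ok)) {
    phi[8] <- if (zmp_term == "max") alpha * max(dev[ok])
              else alpha * trapz(t[ok], dev[ok])
  }

  phi[9] <- alpha * sum(abs(result$qdot[n, ]))

  t_sr <- result$t_seat_release
  win <- if (is.na(t_sr)) n else which(t >= t_sr)
  fy <- result$feet_force[win, 2]
  phi[10] <- alpha * (abs(max(fy) - mg) + abs(min(fy) - mg) +
                      abs(result$feet_force[n, 2] - mg))

  structure(list(alpha = alpha, phi = setNames(phi, paste0("phi", 1:10)),
                 total = sum(weights$w * phi),
                 c0 = c0, cf = cf, c_goal = cg),
            class = "cost_breakdown")
}

#' Weighted total of a cost breakdown
#' @param breakdown `cost_breakdown`
#' @param weights see [default_cost_weights()]
#' @return scalar cost
#' @export
total_cost <- function(breakdown, weights = default_cost_weights()) {
  sum(weights$w * breakdown$phi)
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("STS cost: total %.4f, alpha %.4f\n", x$total, x$alpha))
  print(round(x$phi, 6))
  invisible(x)
}
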