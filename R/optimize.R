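#' Optimize a sit-to-stand excitation trajectory
#'
#' Single-shooting trajectory optimization: the decision vector (piecewise-
#' linear excitation nodes for every actuator plus the movement duration) is
#' searched with active CMA-ES against the ten-term roll-out cost, starting
#' from the sitting initial guess. Genes live on \[0, 1\]; the duration gene
#' is affinely mapped onto `(node_dt, t_max]`. Out-of-range genes are clamped
#' before decoding and penalized quadratically so the sampler stays informed.
#'
#' @param model `planar_model`
#' @param layout `control_layout`; defaults to the model's actuators on a
#'   1.6 s horizon with 0.1 s nodes
#' @param weights cost weights, see [default_cost_weights()]
#' @param config `optimizer_config`
#' @return object of class `sts_optimization`: best controller, its roll-out
#'   and cost breakdown, per-generation history and the restart log
#' @export
optimize_sts <- function(model, layout = control_layout(model),
                         weights = default_cost_weights(layout$t_max),
                         config = optimizer_config()) {
  n <- layout$size
  tf_min <- layout$t_f_min
  tf_span <- layout$t_max - tf_min

  to_decision <- function(x) {
    c(x[-n], tf_min + x[n] * tf_span)
  }

  problem <- function(x) {
    xc <- pmin(1, pmax(0, x))
    pen <- config$bound_penalty * sum((x - xc)^2)
    traj <- decode_controls(to_decision(xc), layout)
    sim <- simulate_sts(model, traj)
    bd <- compute_cost(sim, model, weights)
    list(value = bd$total + pen,
         info = list(alpha = bd$alpha, phi = bd$phi, total = bd$total,
                     t_f = traj$t_f, failed = isTRUE(sim$failed)))
  }

  x0 <- sitting_guess(layout)
  x0_internal <- c(x0[-n], (x0[n] - tf_min) / tf_span)

  res <- run_cmaes(problem, x0_internal, config)

  best_traj <- decode_controls(to_decision(pmin(1, pmax(0, res$best_x))),
                               layout)
  best_sim <- simulate_sts(model, best_traj)
  best_bd <- compute_cost(best_sim, model, weights)

  hist <- res$history
  hist$alpha <- vapply(res$history_info, function(i)
    if (is.null(i)) NA_real_ else i$alpha, 0)
  hist$t_f <- vapply(res$history_info, function(i)
    if (is.null(i)) NA_real_ else i$t_f, 0)

  structure(list(
    best_vector = encode_controls(best_traj),
    best_cost = res$best_f,
    best_trajectory = best_traj,
    best_result = best_sim,
    best_breakdown = best_bd,
    history = hist,
    restart_log = res$restart_log,
    layout = layout, weights = weights, config = config
  ), class = "sts_optimization")
}

#' @export
print.sts_optimization <- function(x, ...) {
  cat(sprintf("STS trajectory optimization: %d generations over %d run(s)\n",
              nrow(x$history), length(x$restart_log)))
  cat(sprintf("  best cost %.3f, alpha %.4f, t_f %.3f s\n",
              x$best_cost, x$best_breakdown$alpha, x$best_trajectory$t_f))
  sr <- x$best_result$t_seat_release
  cat(if (is.na(sr)) "  seat never released\n"
      else sprintf("  seat released at %.3f s\n", sr))
  invisible(x)
}

#' Did a roll-out achieve a successful sit-to-stand?
#'
#' Success requires near-complete COM progress to the standing goal
#' (`alpha > 0.9`), a released seat constraint, no integrator failure, and
#' correctly ordered movement phases.
#'
#' @param opt `sts_optimization` (or pass `result` + `breakdown` directly)
#' @param alpha_min progress threshold
#' @return logical with attribute `checks`
#' @export
sts_success <- function(opt, alpha_min = 0.9) {
  res <- opt$best_result
  bd <- opt$best_breakdown
  released <- !is.na(res$t_seat_release)
  phases_ok <- FALSE
  if (released) {
    ph <- try(segment_phases(res), silent = TRUE)
    phases_ok <- !inherits(ph, "try-error") &&
      ph$t_phase1_end <= ph$t_phase2_end &&
      ph$t_phase2_end <= ph$t_phase3_end
  }
  ok <- bd$alpha > alpha_min && released && !isTRUE(res$failed) && phases_ok
  structure(ok, checks = c(alpha = bd$alpha > alpha_min, released = released,
                           not_failed = !isTRUE(res$failed),
                           phases = phases_ok))
}
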