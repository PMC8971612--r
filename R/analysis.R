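#' Resultant joint torques by inverse dynamics
#'
#' Inverse dynamics of the recorded kinematics with muscles excluded and the
#' seat-constraint and assistance forces supplied as external forces: the
#' per-DOF generalized-force residual equals the net torque the muscles and
#' passive structures produced. Uses the recorded accelerations when present
#' (exact inverse of the roll-out); otherwise differentiates the recorded
#' joint rates numerically.
#'
#' @param result `sts_simulation`
#' @param model `planar_model`
#' @return n x 3 matrix of joint torques (N m)
#' @export
resultant_joint_torques <- function(result, model) {
  qdd <- result$qddot
  if (is.null(qdd)) {
    qdd <- apply(result$qdot, 2, function(v) time_deriv(result$times, v))
  }
  inverse_dynamics(model, result$q, result$qdot, qdd,
                   seat_force = result$seat_force,
                   assist_force = result$assist_force)
}

#' Muscle contributions to the resultant joint torques
#'
#' Decomposes the joint torques of a roll-out into per-muscle contributions
#' (`tendon force x moment arm`), limit-spring torques and the generalized
#' torque equivalent of the assistance force.
#'
#' @param result `sts_simulation`
#' @param model `planar_model`
#' @return object of class `torque_decomposition`: `resultant` (n x 3),
#'   `per_muscle` (n x muscles x 3 array), `limit_spring` (n x 3) and
#'   `assist_equivalent` (n x 3)
#' @export
muscle_torque_contributions <- function(result, model) {
  arms <- cpp_muscle_arms_batch(model$cpp, result$q)
  n <- nrow(result$q)
  n_mus <- nrow(model$muscles)
  per <- array(0, dim = c(n, n_mus, 3),
               dimnames = list(NULL, model$muscles$name, JOINTS))
  for (m in seq_len(n_mus))
    for (j in 1:3)
      per[, m, j] <- result$muscle_force[, m] * arms[, m, j]
  id <- cpp_inverse_dynamics(model$cpp, result$q, result$qdot, result$qddot,
                             rbind2mat(result$seat_force, 2),
                             rbind2mat(result$assist_force, 2))
  resultant <- id$residual
  colnames(resultant) <- JOINTS
  assist_eq <- id$assist_equivalent
  colnames(assist_eq) <- JOINTS
  structure(list(resultant = resultant, per_muscle = per,
                 limit_spring = result$limit_torque,
                 assist_equivalent = assist_eq),
            class = "torque_decomposition")
}

#' Segment a successful roll-out into the three STS phases
#'
#' Phase 1 (trunk flexion) ends at seat release; phase 2 (rise) ends at
#' maximal hip flexion after release; phase 3 (trunk extension) ends at
#' `t_f`.
#'
#' @param result `sts_simulation`
#' @return list with `t_phase1_end`, `t_phase2_end`, `t_phase3_end`
#' @export
segment_phases <- function(result) {
  if (is.na(result$t_seat_release))
    stop("phase segmentation undefined: the seat was never released ",
         "(failed sit-to-stand)", call. = FALSE)
  t <- result$times
  i_rel <- which(t >= result$t_seat_release)[1]
  hip <- result$q[, "hip"]
  i_max <- i_rel - 1 + which.max(hip[i_rel:length(t)])
  list(t_phase1_end = result$t_seat_release,
       t_phase2_end = t[i_max],
       t_phase3_end = t[length(t)])
}

#' EMG envelope processing
#'
#' Fourth-order Butterworth band-pass (10-350 Hz), rectification, fourth-order
#' Butterworth low-pass (3 Hz) and normalization by the maximum-voluntary-
#' contraction peak. Filtering is zero-phase (forward-backward) so envelope
#' timing stays aligned with the kinematics.
#'
#' @param x raw EMG samples
#' @param fs sampling rate (Hz); must exceed 700 Hz so the 350 Hz band edge
#'   is below Nyquist
#' @param mvc_peak normalization peak (same units as `x`)
#' @param band band-pass cutoffs (Hz)
#' @param lowpass envelope cutoff (Hz)
#' @return normalized envelope (same length as `x`)
#' @export
process_emg <- function(x, fs, mvc_peak, band = c(10, 350), lowpass = 3) {
  if (fs <= 2 * band[2])
    stop("sampling rate ", fs, " Hz violates the Nyquist limit for the ",
         band[2], " Hz band edge (need fs > ", 2 * band[2], " Hz)",
         call. = FALSE)
  stopifnot(mvc_peak > 0)
  bp <- signal::butter(4, band / (fs / 2), type = "pass")
  lp <- signal::butter(4, lowpass / (fs / 2), type = "low")
  y <- signal::filtfilt(bp, x)
  y <- abs(y)
  env <- signal::filtfilt(lp, y)
  env / mvc_peak
}

#' Detect sit-to-stand start and end from the hip angle
#'
#' The movement starts when the hip flexion velocity (smoothed with a
#' centered 0.1 s moving average) first exceeds the threshold and ends when
#' the subsequent hip extension velocity falls back below it.
#'
#' @param hip_angle hip angle series (degrees, flexion positive)
#' @param fs sampling rate (Hz)
#' @param threshold velocity threshold (degrees/s)
#' @param window smoothing window (s)
#' @return list with `t_start` and `t_end` (s; `NA` when no event is found)
#' @export
detect_sts_events <- function(hip_angle, fs, threshold = 20, window = 0.1) {
  n <- length(hip_angle)
  stopifnot(n / fs > 0.2)
  t <- (seq_len(n) - 1) / fs
  vel <- time_deriv(t, hip_angle)
  k <- max(1, round(window * fs))
  if (k %% 2 == 0) k <- k + 1
  vs <- as.numeric(stats::filter(vel, rep(1 / k, k), sides = 2))
  vs[is.na(vs)] <- 0
  i_start <- which(vs > threshold)[1]
  if (is.na(i_start)) return(list(t_start = NA_real_, t_end = NA_real_))
  i_ext <- which(vs < -threshold & t > t[i_start])[1]
  if (is.na(i_ext)) return(list(t_start = t[i_start], t_end = NA_real_))
  i_end <- which(vs > -threshold & t > t[i_ext])[1]
  list(t_start = t[i_start],
       t_end = if (is.na(i_end)) NA_real_ else t[i_end])
}

#' Summary table of a sit-to-stand roll-out
#'
#' Movement duration, peak COM velocities, peak resultant hip/knee torques,
#' peak muscle forces and the muscle contributions to the peak resultant
#' torques (as percentages), in the format used to compare strength-deficit
#' conditions.
#'
#' @param result `sts_simulation`
#' @param model `planar_model`
#' @return named list
#' @export
sts_summary <- function(result, model) {
  dec <- muscle_torque_contributions(result, model)
  res <- dec$resultant
  peak_signed <- function(x) x[which.max(abs(x))]
  i_hip_pk <- which.max(abs(res[, "hip"]))
  i_knee_pk <- which.max(abs(res[, "knee"]))
  contrib_pct <- function(muscle, joint, i_pk) {
    100 * peak_signed(dec$per_muscle[, muscle, joint]) / res[i_pk, joint]
  }
  list(
    sts_duration = result$t_f,
    t_seat_release = result$t_seat_release,
    peak_com_horizontal_velocity = max(abs(result$com_vel[, 1])),
    peak_com_vertical_velocity = max(abs(result$com_vel[, 2])),
    peak_hip_torque = peak_signed(res[, "hip"]),
    peak_knee_torque = peak_signed(res[, "knee"]),
    peak_muscle_force = apply(result$muscle_force, 2, max),
    gmax_peak_hip_torque = peak_signed(dec$per_muscle[, "GMAX", "hip"]),
    hams_peak_hip_torque = peak_signed(dec$per_muscle[, "HAMS", "hip"]),
    vas_peak_knee_torque = peak_signed(dec$per_muscle[, "VAS", "knee"]),
    hams_peak_knee_torque = peak_signed(dec$per_muscle[, "HAMS", "knee"]),
    hams_hip_contribution_pct = contrib_pct("HAMS", "hip", i_hip_pk),
    hams_knee_contribution_pct = contrib_pct("HAMS", "knee", i_knee_pk)
  )
}
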