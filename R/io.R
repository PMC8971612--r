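#' Write a time-series table as an OpenSim Storage (.sto/.mot) file
#'
#' Tab-separated text with the standard header (`name`, `nRows=`,
#' `nColumns=`, `inDegrees=`, `endheader`), time column first. For `.mot`
#' files angle columns are conventionally stored in degrees: set
#' `in_degrees = TRUE` and pass data already converted.
#'
#' @param data data.frame whose first column is `time`
#' @param path output path
#' @param name table name in the header
#' @param in_degrees header flag
#' @return `path`, invisibly
#' @export
write_sto <- function(data, path, name = "sitstand", in_degrees = FALSE) {
  stopifnot(names(data)[1] == "time")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name,
               sprintf("nRows=%d", nrow(data)),
               sprintf("nColumns=%d", ncol(data)),
               sprintf("inDegrees=%s", if (in_degrees) "yes" else "no"),
               "endheader",
               paste(names(data), collapse = "\t")), con)
  write.table(format(data, digits = 17, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an OpenSim Storage (.sto/.mot) file
#' @param path file path
#' @return data.frame with attributes `name` and `in_degrees`
#' @export
read_sto <- function(path) {
  lines <- readLines(path)
  hdr_end <- which(trimws(lines) == "endheader")[1]
  if (is.na(hdr_end))
    stop("malformed Storage header in '", path, "': no 'endheader' line",
         call. = FALSE)
  hdr <- lines[seq_len(hdr_end - 1)]
  get_field <- function(key) {
    ln <- grep(paste0("^", key, "="), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    sub(paste0("^", key, "="), "", ln[1])
  }
  n_rows <- as.integer(get_field("nRows"))
  n_cols <- as.integer(get_field("nColumns"))
  labels <- strsplit(trimws(lines[hdr_end + 1]), "\t")[[1]]
  if (!is.na(n_cols) && length(labels) != n_cols)
    stop("malformed Storage header in '", path, "' (line ", hdr_end + 1,
         "): ", length(labels), " column labels but nColumns=", n_cols,
         call. = FALSE)
  body <- lines[(hdr_end + 2):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (!is.na(n_rows) && length(body) != n_rows)
    stop("malformed Storage file '", path, "': ", length(body),
         " data rows but nRows=", n_rows, call. = FALSE)
  df <- read.table(text = body, sep = "\t", col.names = labels,
                   check.names = FALSE)
  attr(df, "name") <- hdr[1]
  attr(df, "in_degrees") <- identical(get_field("inDegrees"), "yes")
  df
}

#' Export a roll-out as a tidy per-sample table
#'
#' One row per sample: time, joint angles/rates, activations, muscle forces,
#' seat and feet reactions, COM, ZMP and assistance force.
#'
#' @param result `sts_simulation`
#' @return data.frame
#' @export
simulation_table <- function(result) {
  mus <- result$muscle_names
  df <- data.frame(time = result$times)
  for (j in 1:3) df[[paste0("q_", JOINTS[j])]] <- result$q[, j]
  for (j in 1:3) df[[paste0("qdot_", JOINTS[j])]] <- result$qdot[, j]
  act <- result$activations
  act_names <- c(mus, if (ncol(act) > length(mus)) c("ASSIST_X", "ASSIST_Y"))
  for (k in seq_len(ncol(act))) df[[paste0("act_", act_names[k])]] <- act[, k]
  for (k in seq_along(mus)) {
    df[[paste0("force_", mus[k])]] <- result$muscle_force[, k]
  }
  df$seat_fx <- result$seat_force[, 1]
  df$seat_fy <- result$seat_force[, 2]
  df$feet_fx <- result$feet_force[, 1]
  df$feet_fy <- result$feet_force[, 2]
  df$feet_moment <- result$feet_moment
  df$com_x <- result$com[, 1]
  df$com_y <- result$com[, 2]
  df$comv_x <- result$com_vel[, 1]
  df$comv_y <- result$com_vel[, 2]
  df$zmp_x <- result$zmp_x
  df$assist_fx <- result$assist_force[, 1]
  df$assist_fy <- result$assist_force[, 2]
  df
}

#' Write a reproducible run bundle
#'
#' Directory with the configuration snapshot (YAML), the roll-out series
#' (CSV), run metadata and the cost breakdown (JSON), and - when an
#' optimization result is given - the per-generation history (CSV) and the
#' best controller (CSV).
#'
#' @param dir output directory (created if needed)
#' @param model `planar_model`
#' @param result `sts_simulation`
#' @param breakdown optional `cost_breakdown`
#' @param optimization optional `sts_optimization`
#' @return `dir`, invisibly
#' @export
write_run_bundle <- function(dir, model, result, breakdown = NULL,
                             optimization = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model_config(model$config, file.path(dir, "config.yaml"))
  write.csv(simulation_table(result), file.path(dir, "simulation.csv"),
            row.names = FALSE)
  meta <- list(t_f = result$t_f, t_seat_release = result$t_seat_release,
               failed = isTRUE(result$failed), mg = result$mg)
  if (!is.null(breakdown))
    meta$cost <- list(alpha = breakdown$alpha,
                      phi = as.list(breakdown$phi), total = breakdown$total)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(optimization)) {
    write.csv(optimization$history, file.path(dir, "history.csv"),
              row.names = FALSE)
    write_controls_csv(optimization$best_trajectory,
                       file.path(dir, "best_controls.csv"))
  }
  invisible(dir)
}

#' Generate deterministic test fixtures
#'
#' * `default_model`: the default model configuration (YAML).
#' * `deficit_sweep`: five configurations at strength scales 1.0, 0.8, 0.6,
#'   0.4, 0.2 (strength deficits in steps of 20\%).
#' * `toy_trajectory`: a short passive roll-out exported as CSV.
#' * `synthetic_emg`: seeded band-limited EMG-like bursts with a known MVC
#'   peak (CSV: time, emg; attributes in a JSON side file).
#' * `synthetic_reference`: a smooth (minimum-jerk) seated-to-upright joint
#'   trajectory with a decaying synthetic seat-force profile, for tracking.
#'
#' @param kind fixture kind
#' @param seed RNG seed
#' @param dir output directory
#' @return character vector of the files written
#' @export
make_fixture <- function(kind = c("default_model", "deficit_sweep",
                                  "toy_trajectory", "synthetic_emg",
                                  "synthetic_reference"),
                         seed = 1L, dir = tempdir()) {
  kind <- tryCatch(match.arg(kind), error = function(e)
    stop("unknown fixture kind '", kind[1], "'; available: default_model, ",
         "deficit_sweep, toy_trajectory, synthetic_emg, synthetic_reference",
         call. = FALSE))
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  switch(kind,
    default_model = {
      f <- file.path(dir, "default_model.yaml")
      write_model_config(default_model_config(), f)
      f
    },
    deficit_sweep = {
      scales <- c(1.0, 0.8, 0.6, 0.4, 0.2)
      vapply(scales, function(s) {
        f <- file.path(dir, sprintf("model_scale_%03d.yaml", round(100 * s)))
        write_model_config(default_model_config(strength_scale = s), f)
        f
      }, "")
    },
    toy_trajectory = {
      model <- build_model()
      layout <- control_layout(model, t_max = 0.4)
      traj <- decode_controls(sitting_guess(layout), layout)
      sim <- simulate_sts(model, traj)
      f <- file.path(dir, "toy_trajectory.csv")
      write.csv(simulation_table(sim), f, row.names = FALSE)
      f
    },
    synthetic_emg = {
      fs <- 2000
      t <- seq(0, 3, by = 1 / fs)
      carrier <- rowSums(vapply(c(35, 60, 95, 140), function(fr)
        sin(2 * pi * fr * t + stats::runif(1, 0, 2 * pi)), t))
      burst <- exp(-((t - 1.0) / 0.25)^2) + 0.6 * exp(-((t - 2.0) / 0.2)^2)
      emg <- carrier * burst + 0.05 * stats::rnorm(length(t))
      mvc <- max(abs(emg)) * 1.25
      f <- file.path(dir, "synthetic_emg.csv")
      write.csv(data.frame(time = t, emg = emg), f, row.names = FALSE)
      j <- file.path(dir, "synthetic_emg.json")
      jsonlite::write_json(list(fs = fs, mvc_peak = mvc, seed = seed), j,
                           auto_unbox = TRUE, digits = NA)
      c(f, j)
    },
    synthetic_reference = {
      model <- build_model()
      dur <- 1.2
      t <- seq(0, dur, by = 0.01)
      s <- t / dur
      minjerk <- 10 * s^3 - 15 * s^4 + 6 * s^5
      qmat <- outer(1 - minjerk, model$q0)
      mg <- model$mass_total * model$gravity
      seat_fy <- pmax(0, 0.6 * mg * (1 - t / 0.45))
      f <- file.path(dir, "synthetic_reference.csv")
      write.csv(data.frame(time = t, q_ankle = qmat[, 1], q_knee = qmat[, 2],
                           q_hip = qmat[, 3], seat_fx = 0,
                           seat_fy = seat_fy), f, row.names = FALSE)
      f
    })
}

#' Write / read joint kinematics as an OpenSim motion (.mot) file
#'
#' Angles are stored in degrees on disk (the .mot convention) and handled in
#' radians in memory.
#'
#' @param times time grid (s)
#' @param q n x 3 joint angles (rad)
#' @param path output path
#' @return `path` invisibly / a list with `times` and `q` (rad)
#' @export
write_motion <- function(times, q, path) {
  q <- rbind2mat(q)
  df <- data.frame(time = times, q * 180 / pi)
  names(df) <- c("time", paste0("q_", JOINTS))
  write_sto(df, path, name = "sitstand_motion", in_degrees = TRUE)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  df <- read_sto(path)
  stopifnot(isTRUE(attr(df, "in_degrees")))
  list(times = df$time,
       q = as.matrix(df[, paste0("q_", JOINTS)]) * pi / 180)
}
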