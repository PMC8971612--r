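#' Size of the trajectory-optimization decision vector
#'
#' One gene per actuator per excitation node (nodes every `dt` seconds from
#' `dt` to `t_max`; the value at time zero is the default activation, not a
#' decision variable) plus one gene for the movement duration `t_f`.
#' With 8 muscles, 0.1 s nodes and a 1.6 s horizon this gives 129 variables;
#' adding the two assistance actuators gives 161.
#'
#' @param n_actuators number of controlled actuators
#' @param t_max simulation horizon (s)
#' @param dt node spacing (s)
#' @return integer count
#' @export
decision_vector_size <- function(n_actuators, t_max = 1.6, dt = 0.1) {
  k <- t_max / dt
  if (abs(k - round(k)) > 1e-9)
    stop("t_max must be an integer multiple of the node spacing",
         call. = FALSE)
  as.integer(n_actuators * round(k) + 1L)
}

#' Control layout for a model
#'
#' Describes the decision-vector encoding: actuator names (muscles plus, in
#' assisted mode, the horizontal and vertical assistance actuators), node
#' grid, default activations at time zero and the admissible `t_f` range.
#'
#' @param model `planar_model`
#' @param t_max horizon (s)
#' @param node_dt node spacing (s)
#' @param t_f_min shortest admissible movement duration (s); decoded `t_f`
#'   genes are clamped into `[t_f_min, t_max]`. The default keeps durations
#'   in the physiological sit-to-stand range (experimental STS takes about a
#'   second), which also stops the optimizer from ending roll-outs mid-fall.
#' @return object of class `control_layout`
#' @export
control_layout <- function(model, t_max = 1.6, node_dt = 0.1,
                           t_f_min = 0.8) {
  names <- model$muscles$name
  defaults <- rep(model$act_default, length(names))
  if (isTRUE(model$assist$on)) {
    names <- c(names, "ASSIST_X", "ASSIST_Y")
    defaults <- c(defaults, 0, 0)
  }
  structure(list(
    actuator_names = names, n_act = length(names),
    t_max = t_max, node_dt = node_dt,
    n_nodes = as.integer(round(t_max / node_dt)),
    act_default = defaults,
    t_f_min = min(t_f_min, t_max),
    size = decision_vector_size(length(names), t_max, node_dt)
  ), class = "control_layout")
}

#' Construct a piecewise-linear excitation controller
#'
#' @param nodes actuators x nodes matrix of excitation values in \[0, 1\];
#'   node `k` sits at time `k * node_dt`
#' @param t_f roll-out duration (s)
#' @param layout `control_layout`
#' @return object of class `control_trajectory`
#' @export
control_trajectory <- function(nodes, t_f, layout) {
  nodes <- as.matrix(nodes)
  stopifnot(nrow(nodes) == layout$n_act, ncol(nodes) == layout$n_nodes)
  if (any(nodes < 0 | nodes > 1))
    stop("excitation node values must lie in [0, 1]", call. = FALSE)
  if (t_f < 0 || t_f > layout$t_max)
    stop("t_f must lie in [0, t_max]", call. = FALSE)
  structure(list(
    nodes = nodes, t_f = t_f, node_dt = layout$node_dt,
    node_times = seq_len(layout$n_nodes) * layout$node_dt,
    actuator_names = layout$actuator_names,
    act_default = layout$act_default, t_max = layout$t_max
  ), class = "control_trajectory")
}

#' Encode a controller as a flat decision vector
#'
#' Genes are the node values in column-major node order (all actuators at
#' node 1, then node 2, ...) followed by `t_f`. `decode_controls()` inverts
#' the encoding; out-of-range genes are clamped to \[0, 1\] (nodes) and to
#' `(node_dt, t_max]` (`t_f`), and the number of clamped genes is recorded in
#' the `clamped` attribute.
#'
#' @param traj `control_trajectory`
#' @return numeric decision vector
#' @export
encode_controls <- function(traj) {
  c(as.vector(traj$nodes), traj$t_f)
}

#' @rdname encode_controls
#' @param x decision vector
#' @param layout `control_layout`
#' @export
decode_controls <- function(x, layout) {
  if (length(x) != layout$size)
    stop("decision vector has length ", length(x), "; layout needs ",
         layout$size, call. = FALSE)
  genes <- x[-length(x)]
  t_f <- x[length(x)]
  clamped <- sum(genes < 0 | genes > 1) +
    (t_f < layout$t_f_min || t_f > layout$t_max)
  nodes <- matrix(pmin(1, pmax(0, genes)), layout$n_act, layout$n_nodes)
  t_f <- min(max(t_f, layout$t_f_min), layout$t_max)
  out <- control_trajectory(nodes, t_f, layout)
  attr(out, "clamped") <- as.integer(clamped)
  out
}

#' Excitation values at a time point
#'
#' Linear interpolation between the default activation at time zero and the
#' node values; exact at node times.
#'
#' @param traj `control_trajectory`
#' @param t time (s), `0 <= t <= t_f`
#' @return per-actuator excitation vector
#' @export
excitation_at <- function(traj, t) {
  if (t < 0 || t > traj$t_f)
    stop("t must lie within [0, t_f]", call. = FALSE)
  s <- t / traj$node_dt
  n <- ncol(traj$nodes)
  if (s >= n) return(setNames(traj$nodes[, n], traj$actuator_names))
  k <- floor(s); f <- s - k
  lo <- if (k == 0) traj$act_default else traj$nodes[, k]
  hi <- traj$nodes[, k + 1]
  setNames(lo + f * (hi - lo), traj$actuator_names)
}

#' Assistance point force for an activation level
#'
#' Each of the two assistance actuators produces
#' `activation * f_max * direction` at the torso centre of mass, with the
#' magnitude therefore bounded by `f_max` (200 N by default). Excitations are
#' smoothed by first-order activation dynamics with a 0.1 s time constant
#' before they become forces.
#'
#' @param activation activation in \[0, 1\]
#' @param direction unit 2D vector (`c(1,0)` horizontal, `c(0,1)` vertical)
#' @param f_max force cap (N)
#' @return 2D force (N)
#' @export
assist_force_at <- function(activation, direction = c(0, 1), f_max = 200) {
  stopifnot(activation >= 0, activation <= 1,
            abs(sum(direction^2) - 1) < 1e-9)
  activation * f_max * direction
}

#' Decision vector for the model sitting still
#'
#' All muscle nodes at the default activation, assistance nodes at zero and
#' `t_f` at the horizon: the initial guess for the optimizer mean.
#'
#' @param layout `control_layout`
#' @return numeric decision vector
#' @export
sitting_guess <- function(layout) {
  c(rep(layout$act_default, layout$n_nodes), layout$t_max)
}

#' @export
print.control_trajectory <- function(x, ...) {
  cat(sprintf("piecewise-linear controller: %d actuators, %d nodes every %.2g s, t_f = %.3f s\n",
              nrow(x$nodes), ncol(x$nodes), x$node_dt, x$t_f))
  invisible(x)
}

#' Write / read a controller as CSV (time column + one column per actuator)
#' @param traj `control_trajectory`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_controls_csv <- function(traj, path) {
  df <- data.frame(time = c(0, traj$node_times),
                   rbind(traj$act_default, t(traj$nodes)))
  names(df) <- c("time", traj$actuator_names)
  attr_line <- sprintf("# t_f=%.17g node_dt=%.17g t_max=%.17g",
                       traj$t_f, traj$node_dt, traj$t_max)
  con <- file(path, "w")
  writeLines(attr_line, con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_controls_csv
#' @param layout `control_layout` the file must match
#' @export
read_controls_csv <- function(path, layout) {
  first <- readLines(path, n = 1)
  t_f <- as.numeric(sub(".*t_f=([0-9.eE+-]+).*", "\\1", first))
  df <- read.csv(path, skip = 1, check.names = FALSE)
  nodes <- t(as.matrix(df[-1, -1, drop = FALSE]))
  control_trajectory(unname(nodes), t_f, layout)
}
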