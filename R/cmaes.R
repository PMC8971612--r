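# Active CMA-ES (covariance matrix adaptation evolution strategy with a
# negative-weight "active" covariance update), implemented after Hansen's
# standard formulation. Used as the search engine for the sit-to-stand
# excitation-trajectory optimization; kept generic so it can be unit-tested
# on analytic functions.

#' Optimizer configuration
#'
#' Defaults follow the framework's stopping and restart policy: a run is
#' restarted when it exceeds `max_generations` or when the best cost improves
#' by less than `stagnation_delta` over the last `stagnation_window`
#' generations; at each restart the covariance and step size are reset and
#' the mean is set to the best candidate seen so far. `n_restarts` restarts
#' are performed in total. Population size defaults to `4 + floor(3 log n)`
#' and the initial step size to 0.15 on the unit-scaled genes.
#'
#' @param max_generations generation cap per run
#' @param stagnation_window,stagnation_delta stagnation restart rule
#' @param n_restarts number of restarts after the first run
#' @param population_size lambda (NULL: CMA-ES default)
#' @param initial_sigma initial step size on \[0, 1\]-scaled genes
#' @param seed RNG seed (integer) for reproducible runs
#' @param bound_penalty quadratic out-of-bounds penalty weight
#' @param active use the active (negative-weight) covariance update
#' @param diagonal adapt only a diagonal covariance (separable CMA-ES);
#'   markedly faster adaptation for large decision vectors under tight
#'   evaluation budgets, at the price of ignoring gene couplings
#' @return list of class `optimizer_config`
#' @export
optimizer_config <- function(max_generations = 4000, stagnation_window = 250,
                             stagnation_delta = 1.0, n_restarts = 4,
                             population_size = NULL, initial_sigma = 0.15,
                             seed = 1L, bound_penalty = 1000,
                             active = TRUE, diagonal = FALSE) {
  stopifnot(max_generations > 0, stagnation_window > 0, n_restarts >= 0)
  structure(list(max_generations = max_generations,
                 stagnation_window = stagnation_window,
                 stagnation_delta = stagnation_delta,
                 n_restarts = n_restarts, population_size = population_size,
                 initial_sigma = initial_sigma, seed = seed,
                 bound_penalty = bound_penalty, active = active,
                 diagonal = diagonal),
            class = "optimizer_config")
}

#' Stagnation test on a window of best costs
#'
#' @param best_costs best cost per generation (most recent last)
#' @param window span of the improvement test (generations); the earliest
#'   possible trigger is generation `window + 1`
#' @param delta minimal improvement; restart fires when the improvement over
#'   the window (cost `window` generations ago minus current) is strictly
#'   below `delta`
#' @return logical
#' @export
stagnation_check <- function(best_costs, window = 250, delta = 1.0) {
  n <- length(best_costs)
  if (n < window + 1) return(FALSE)
  (best_costs[n - window] - best_costs[n]) < delta
}

# one CMA-ES run (no restarts). fn may return a scalar or
# list(value=, info=); non-finite values are replaced by a large penalty.
cmaes_run <- function(fn, x0, sigma0, max_generations, lambda = NULL,
                      stagnation_window = Inf, stagnation_delta = 0,
                      active = TRUE, stop_fitness = -Inf, diagonal = FALSE) {
  n <- length(x0)
  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  mu <- floor(lambda / 2)
  wp <- log((lambda + 1) / 2) - log(seq_len(lambda))
  mueff <- sum(wp[1:mu])^2 / sum(wp[1:mu]^2)
  mueff_neg <- sum(wp[(mu + 1):lambda])^2 / sum(wp[(mu + 1):lambda]^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  if (diagonal) cmu <- min(1 - c1, cmu * (n + 2) / 3)  # sep-CMA speed-up
  ds <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  w <- wp
  w[1:mu] <- wp[1:mu] / sum(wp[1:mu])
  if (active) {
    amu <- 1 + c1 / cmu
    amueff <- 1 + 2 * mueff_neg / (mueff + 2)
    apd <- (1 - c1 - cmu) / (n * cmu)
    w[(mu + 1):lambda] <- wp[(mu + 1):lambda] *
      min(amu, amueff, apd) / (-sum(wp[(mu + 1):lambda]))
  } else {
    w[(mu + 1):lambda] <- 0
  }
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  m <- x0
  sigma <- sigma0
  Cdiag <- rep(1, n)                    # diagonal (separable) representation
  C <- if (diagonal) NULL else diag(n)
  B <- if (diagonal) NULL else diag(n)
  D <- rep(1, n)
  invsqrtC <- if (diagonal) NULL else diag(n)
  ps <- pc <- rep(0, n)
  eig_gap <- max(1, floor(1 / ((c1 + cmu) * n * 10)))
  last_eig <- 0

  best_x <- x0; best_f <- Inf; best_info <- NULL
  hist_best <- hist_mean <- numeric(0)
  hist_info <- list()
  gen <- 0L
  stopped <- "max_generations"

  while (gen < max_generations) {
    gen <- gen + 1L
    Z <- matrix(stats::rnorm(lambda * n), n, lambda)
    Y <- if (diagonal) D * Z else B %*% (D * Z)
    X <- m + sigma * Y
    fs <- numeric(lambda); infos <- vector("list", lambda)
    for (k in seq_len(lambda)) {
      r <- fn(X[, k])
      if (is.list(r)) { fs[k] <- r$value; infos[[k]] <- r$info }
      else fs[k] <- r
      if (!is.finite(fs[k])) fs[k] <- 1e12
    }
    ord <- order(fs)
    fs_s <- fs[ord]
    Ys <- Y[, ord, drop = FALSE]
    if (fs_s[1] < best_f) {
      best_f <- fs_s[1]; best_x <- X[, ord[1]]; best_info <- infos[[ord[1]]]
    }
    hist_best <- c(hist_best, fs_s[1])
    hist_mean <- c(hist_mean, mean(fs))
    hist_info[[gen]] <- infos[[ord[1]]]

    yw <- as.vector(Ys[, 1:mu, drop = FALSE] %*% w[1:mu])
    m <- m + sigma * yw
    psd <- if (diagonal) yw / D else as.vector(invsqrtC %*% yw)
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * psd
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * gen)) / chiN <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * as.vector(yw)

    wo <- w
    if (active) {
      neg <- (mu + 1):lambda
      zn <- if (diagonal) colSums((Ys[, neg, drop = FALSE] / D)^2)
            else colSums((invsqrtC %*% Ys[, neg, drop = FALSE])^2)
      wo[neg] <- w[neg] * n / pmax(zn, 1e-12)
    }
    dh <- (1 - hsig) * cc * (2 - cc)
    if (diagonal) {
      Cdiag <- (1 + c1 * dh - c1 - cmu * sum(w)) * Cdiag +
        c1 * pc^2 +
        cmu * as.vector(Ys^2 %*% wo)
      Cdiag <- pmax(Cdiag, 1e-20)
      D <- sqrt(Cdiag)
    } else {
      C <- (1 + c1 * dh - c1 - cmu * sum(w)) * C +
        c1 * tcrossprod(pc) +
        cmu * (Ys %*% (wo * t(Ys)))
    }
    sigma <- sigma * exp((cs / ds) * (sqrt(sum(ps^2)) / chiN - 1))
    if (!is.finite(sigma) || sigma > 1e6) sigma <- 1e6

    if (!diagonal && gen - last_eig >= eig_gap) {
      C <- (C + t(C)) / 2
      eg <- eigen(C, symmetric = TRUE)
      D <- sqrt(pmax(eg$values, 1e-20))
      B <- eg$vectors
      invsqrtC <- B %*% ((1 / D) * t(B))
      last_eig <- gen
    }

    if (best_f <= stop_fitness) { stopped <- "stop_fitness"; break }
    bsf <- cummin(hist_best)
    if (is.finite(stagnation_window) &&
        stagnation_check(bsf, stagnation_window, stagnation_delta)) {
      stopped <- "stagnation"; break
    }
  }
  list(best_x = best_x, best_f = best_f, best_info = best_info,
       hist_best = hist_best, hist_mean = hist_mean, hist_info = hist_info,
       generations = gen, stopped = stopped)
}

#' Run CMA-ES with the framework's restart policy
#'
#' Performs an initial run plus up to `n_restarts` restarts; every restart
#' resets the covariance, step size and generation counter and recentres the
#' sampling mean on the best candidate seen so far. Evaluations are
#' sequential so a fixed seed gives bit-identical histories.
#'
#' @param fn objective; may return a scalar or `list(value=, info=)`
#' @param x0 initial mean
#' @param config `optimizer_config`
#' @return list with `best_x`, `best_f`, `best_info`, per-generation
#'   `history` (run, generation, best, mean, best-so-far) and `restart_log`
#' @export
run_cmaes <- function(fn, x0, config = optimizer_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  best_x <- x0; best_f <- Inf; best_info <- NULL
  history <- NULL; infos <- list()
  restart_log <- list()
  for (run in seq_len(config$n_restarts + 1)) {
    r <- cmaes_run(fn, best_x, config$initial_sigma,
                   max_generations = config$max_generations,
                   lambda = config$population_size,
                   stagnation_window = config$stagnation_window,
                   stagnation_delta = config$stagnation_delta,
                   active = config$active,
                   diagonal = isTRUE(config$diagonal))
    if (r$best_f < best_f) {
      best_f <- r$best_f; best_x <- r$best_x; best_info <- r$best_info
    }
    history <- rbind(history, data.frame(
      run = run, generation = seq_along(r$hist_best),
      best = r$hist_best, mean = r$hist_mean))
    infos <- c(infos, r$hist_info)
    restart_log[[run]] <- list(run = run, trigger = r$stopped,
                               generation = r$generations)
    # the next run recentres its mean on best_x (best seen so far)
  }
  history$best_so_far <- cummin(history$best)
  list(best_x = best_x, best_f = best_f, best_info = best_info,
       history = history, history_info = infos, restart_log = restart_log)
}
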