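#' Exact stochastic simulation of one cell
#'
#' Gillespie direct-method simulation of the crosstalk network at system
#' size `Omega`, sampled onto a uniform output grid.  The piecewise-
#' constant stressor is handled exactly: the next-reaction time is
#' truncated at protocol segment boundaries, where propensities are
#' re-evaluated.  The initial condition is the deterministic resting state
#' rounded to molecule counts.
#'
#' If `params$sigma_S > 0` (the calibrated default), the cell experiences
#' the protocol's stressor levels multiplied by a mean-one lognormal factor
#' drawn once per cell: extrinsic variability of the perceived stress
#' strength, on top of the intrinsic copy-number noise of the Gillespie
#' dynamics.  Set `sigma_S = 0` for purely intrinsic noise (as the
#' system-size convergence checks do).
#'
#' @param params an [er_params()] object.
#' @param protocol a [stress_protocol()].
#' @param seed integer seed; the same seed and inputs give a bit-identical
#'   trajectory.
#' @param dt_out output time step (min); default 1.
#' @param state0 optional initial state (concentrations); defaults to the
#'   resting state.
#' @return a `cell_trajectory` data.frame (`t`, `ERSS`, `AUT`,
#'   `APO_1..n`), concentrations on the output grid.
#' @export
simulate_cell <- function(params, protocol, seed, dt_out = 1, state0 = NULL) {
  stopifnot(inherits(params, "er_params"), inherits(protocol, "stress_protocol"))
  if (dt_out <= 0) stop("dt_out must be > 0")
  if (is.null(state0)) state0 <- resting_state(params)
  state0 <- check_state(state0, params)
  x0 <- round(as.numeric(state0) * params$Omega)

  t_grid <- seq(0, protocol$t_end, by = dt_out)
  if (t_grid[length(t_grid)] < protocol$t_end) t_grid <- c(t_grid, protocol$t_end)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  level <- protocol$level
  if (params$sigma_S > 0) {
    level <- level * exp(stats::rnorm(1, -params$sigma_S^2 / 2, params$sigma_S))
  }
  mat <- ssa_simulate_cpp(params, protocol$start, level, protocol$t_end,
                          t_grid, as.integer(x0), as.numeric(params$Omega))
  colnames(mat) <- state_names(params)
  traj <- data.frame(t = t_grid, mat, check.names = FALSE)
  attr(traj, "params") <- params
  attr(traj, "protocol") <- protocol
  attr(traj, "seed") <- as.integer(seed)
  class(traj) <- c("cell_trajectory", "data.frame")
  traj
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Per-cell seeds spawned from a master seed: platform-stable scheme using
# R's own RNG stream (documented: set.seed(master), then n draws from
# sample.int(2^31 - 2)).
spawn_seeds <- function(master_seed, n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

#' Simulate an ensemble of independent cells
#'
#' Runs [simulate_cell()] for `n_cells` cells with per-cell seeds spawned
#' reproducibly from `master_seed`, and annotates each cell with its fate
#' at the end of the horizon and its apoptosis activation time (first
#' crossing of `theta_apo`; cells that never cross are censored at the
#' horizon).
#'
#' @param params an [er_params()] object.
#' @param protocol a [stress_protocol()].
#' @param n_cells number of cells (>= 1); the reference population size is
#'   50.
#' @param master_seed integer master seed; identical master seeds give
#'   bit-identical ensembles.
#' @param dt_out output time step (min).
#' @param theta_aut,theta_apo classification thresholds.
#' @return an `ensemble_result`: list with `trajectories` (list of
#'   `cell_trajectory`), `seeds`, `fate` (factor at horizon),
#'   `activation_time` (min; `NA` while censored — see `censored`),
#'   `censored` (logical), `params`, `protocol`, `master_seed`.
#' @export
simulate_ensemble <- function(params, protocol, n_cells = 50, master_seed,
                              dt_out = 1, theta_aut = 0.5, theta_apo = 0.5) {
  stopifnot(n_cells >= 1)
  seeds <- spawn_seeds(master_seed, n_cells)
  state0 <- resting_state(params)
  apo_col <- paste0("APO_", params$n_steps)

  trajectories <- vector("list", n_cells)
  fate <- character(n_cells)
  act_time <- rep(NA_real_, n_cells)
  censored <- rep(TRUE, n_cells)
  for (i in seq_len(n_cells)) {
    tr <- simulate_cell(params, protocol, seeds[i], dt_out, state0 = state0)
    trajectories[[i]] <- tr
    fate[i] <- classify(tr[nrow(tr), ], params, theta_aut, theta_apo)
    hit <- which(tr[[apo_col]] / params$APO_T > theta_apo)
    if (length(hit)) {
      act_time[i] <- tr$t[hit[1]]
      censored[i] <- FALSE
    }
  }
  structure(list(trajectories = trajectories,
                 seeds = seeds,
                 fate = factor(fate, levels = c("autophagic", "apoptotic", "neither")),
                 activation_time = act_time,
                 censored = censored,
                 params = params, protocol = protocol,
                 master_seed = as.integer(master_seed),
                 theta_aut = theta_aut, theta_apo = theta_apo),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble_result>", length(x$trajectories), "cells, horizon",
      x$protocol$t_end, "min\n")
  print(table(x$fate))
  invisible(x)
}
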