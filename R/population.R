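#' Fate fractions of an ensemble at an evaluation time
#'
#' Classifies every cell of an ensemble at time `t_eval` and returns the
#' fractions of autophagic, apoptotic and neither cells (summing to 1).
#'
#' @param ensemble an `ensemble_result` from [simulate_ensemble()].
#' @param t_eval evaluation time (min), within the simulated horizon;
#'   defaults to the end of the horizon.
#' @param theta_aut,theta_apo classification thresholds.
#' @return named numeric vector
#'   `c(autophagic = , apoptotic = , neither = )`.
#' @export
fate_fractions <- function(ensemble, t_eval = NULL,
                           theta_aut = 0.5, theta_apo = 0.5) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  params <- ensemble$params
  horizon <- ensemble$protocol$t_end
  if (is.null(t_eval)) t_eval <- horizon
  if (t_eval < 0 || t_eval > horizon) {
    stop("t_eval must lie within the simulated horizon [0, ", horizon, "]")
  }
  fates <- vapply(ensemble$trajectories, function(tr) {
    i <- which.min(abs(tr$t - t_eval))
    classify(tr[i, ], params, theta_aut, theta_apo)
  }, character(1))
  n <- length(fates)
  c(autophagic = sum(fates == "autophagic") / n,
    apoptotic = sum(fates == "apoptotic") / n,
    neither = sum(fates == "neither") / n)
}

new_fate_curve <- function(sweep_name, grid, frac, n_cells, master_seed,
                           t_eval, params) {
  df <- data.frame(sweep_value = grid,
                   frac_autophagic = frac[, "autophagic"],
                   frac_apoptotic = frac[, "apoptotic"],
                   frac_neither = frac[, "neither"],
                   n_cells = n_cells, seed = master_seed)
  attr(df, "sweep") <- sweep_name
  attr(df, "t_eval") <- t_eval
  attr(df, "params") <- params
  class(df) <- c("fate_curve", "data.frame")
  df
}

#' Population dose-response: fate fractions across stressor levels
#'
#' For each level of `S_grid`, simulates an independent ensemble under
#' constant treatment and records the fate fractions at `t_eval`.  The
#' reference experiment is an integer scan `S0 = 1..10` with 50 cells per
#' level, 240 min of treatment, fates checked at 240 min: the low levels
#' are autophagy-majority, the high levels apoptosis-majority, and both
#' fates coexist in an intermediate window.
#'
#' @param params an [er_params()] object.
#' @param S_grid stressor levels to scan.
#' @param n_cells cells per level.
#' @param t_end treatment duration (min).
#' @param t_eval evaluation time (min).
#' @param master_seed integer; per-level sub-seeds are spawned from it.
#' @param dt_out output step (min) for the underlying trajectories.
#' @return a `fate_curve` data.frame with columns `sweep_value`,
#'   `frac_autophagic`, `frac_apoptotic`, `frac_neither`, `n_cells`,
#'   `seed`.
#' @export
dose_response_scan <- function(params, S_grid = 1:10, n_cells = 50,
                               t_end = 240, t_eval = 240, master_seed,
                               dt_out = 2) {
  sub_seeds <- spawn_seeds(master_seed + 1L, length(S_grid))
  frac <- t(vapply(seq_along(S_grid), function(i) {
    ens <- simulate_ensemble(params, constant_stress(S_grid[i], t_end),
                             n_cells, sub_seeds[i], dt_out = dt_out)
    fate_fractions(ens, t_eval)
  }, numeric(3)))
  new_fate_curve("S0", S_grid, frac, n_cells, master_seed, t_eval, params)
}

#' Apoptosis activation times of an ensemble
#'
#' Per-cell first-crossing time of the apoptotic threshold; cells that
#' never cross within the horizon are censored there (reported at the
#' horizon with `censored = TRUE`).
#'
#' @param ensemble an `ensemble_result`.
#' @return data.frame with columns `cell`, `time` (min), `censored`.
#' @export
activation_time_distribution <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  horizon <- ensemble$protocol$t_end
  data.frame(cell = seq_along(ensemble$seeds),
             time = ifelse(ensemble$censored, horizon, ensemble$activation_time),
             censored = ensemble$censored)
}

#' Washout commitment curve
#'
#' For each washout time on the grid, applies `S0` until that time,
#' removes the stressor, follows the cells for a further `t_post` minutes
#' and records the fate fractions at the end.  The reference experiment
#' is `S0 = 10`, washout at 15..105 min in 15-min steps, evaluation
#' 120 min after washout, 50 cells per point: commitment to apoptosis is
#' rare at the earliest washout, rises through intermediate washout times
#' and saturates near 95% at the latest one.
#'
#' @param params an [er_params()] object.
#' @param S0 stressor level before washout.
#' @param washout_grid washout times (min).
#' @param t_post follow-up after washout (min).
#' @param n_cells cells per washout time.
#' @param master_seed integer master seed.
#' @param dt_out output step (min).
#' @return a `fate_curve` with `sweep_value` = washout time; the
#'   evaluation time is `t_washout + t_post` for each point.
#' @export
washout_commitment_curve <- function(params, S0 = 10,
                                     washout_grid = seq(15, 105, by = 15),
                                     t_post = 120, n_cells = 50, master_seed,
                                     dt_out = 2) {
  sub_seeds <- spawn_seeds(master_seed + 2L, length(washout_grid))
  frac <- t(vapply(seq_along(washout_grid), function(i) {
    ens <- simulate_ensemble(params, washout(S0, washout_grid[i], t_post),
                             n_cells, sub_seeds[i], dt_out = dt_out)
    fate_fractions(ens)
  }, numeric(3)))
  new_fate_curve("t_washout", washout_grid, frac, n_cells, master_seed,
                 t_post, params)
}

#' Ensemble-mean trajectory
#'
#' Arithmetic mean of all cell trajectories per output time: the
#' population-average signal an immunoblot-style readout would see.  The
#' mean of abruptly switching single cells is a gradual curve when
#' switching times are dispersed.
#'
#' @param ensemble an `ensemble_result`.
#' @return a `cell_trajectory`-shaped data.frame of means.
#' @export
ensemble_mean <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  mats <- lapply(ensemble$trajectories, function(tr) {
    as.matrix(tr[, -1, drop = FALSE])
  })
  m <- Reduce(`+`, mats) / length(mats)
  out <- data.frame(t = ensemble$trajectories[[1]]$t, m, check.names = FALSE)
  attr(out, "params") <- ensemble$params
  attr(out, "protocol") <- ensemble$protocol
  class(out) <- c("cell_trajectory", "data.frame")
  out
}

#' Write a fate curve to CSV (with a JSON provenance sidecar)
#'
#' The CSV has columns
#' `sweep_value,frac_autophagic,frac_apoptotic,frac_neither,n_cells,seed`;
#' the sidecar `<path>.json` records the swept variable, evaluation time,
#' master seed and a hash of the parameter set.
#'
#' @param curve a `fate_curve`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fate_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fate_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  side <- list(sweep = attr(curve, "sweep"),
               t_eval = attr(curve, "t_eval"),
               n_cells = curve$n_cells[1],
               master_seed = curve$seed[1],
               params_hash = params_hash(attr(curve, "params")),
               package_version = as.character(utils::packageVersion("erfate")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
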