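#' Deterministic apoptosis threshold
#'
#' The smallest stressor level at which deterministic integration from the
#' resting state for `t_end` minutes ends in the apoptotic state, located
#' by bisection to the requested resolution.  Below the threshold the cell
#' ends autophagic (or resting); above it the multistep death switch has
#' flipped by `t_end`.
#'
#' @param params an [er_params()] object.
#' @param S_range search interval, default `c(0, 10)`.
#' @param resolution bisection resolution in stress units, default 0.01.
#' @param t_end integration horizon per evaluation (min), default 240.
#' @param theta_apo apoptotic classification threshold.
#' @return the threshold `S*` (stress units), or `NA` if no level in
#'   `S_range` is apoptotic by `t_end`.
#' @export
apoptosis_threshold <- function(params, S_range = c(0, 10), resolution = 0.01,
                                t_end = 240, theta_apo = 0.5) {
  stopifnot(inherits(params, "er_params"))
  rest <- resting_state(params)
  apoptotic_at <- function(S) {
    tr <- integrate_protocol(params, constant_stress(S, t_end), rest,
                             dt_out = t_end)
    classify(tr[nrow(tr), ], params, theta_apo = theta_apo) == "apoptotic"
  }
  lo <- S_range[1]; hi <- S_range[2]
  if (apoptotic_at(lo)) return(lo)
  if (!apoptotic_at(hi)) return(NA_real_)
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (apoptotic_at(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Quasi-static hysteresis scan
#'
#' Slowly ramps the stressor up and then down, re-equilibrating the model
#' at every level for a fixed dwell time (default 500 min) starting from
#' the state reached at the previous level.  The upward scan from the
#' resting state locates the activation level `S_on` (first level ending
#' apoptotic); the downward scan from the apoptotic state locates the
#' deactivation level `S_off` (last level still apoptotic; one grid step
#' below it the cell reverts).  The system is bistable when `S_off < S_on`
#' and the apoptotic state is reported irreversible when it persists
#' through the dwell at `S = 0` (point of no return: with the positive
#' feedback engaged the death state outlives any finite observation
#' window even though the stressor is gone).
#'
#' @param params an [er_params()] object.
#' @param S_up_grid,S_down_grid levels of the upward and downward scans.
#' @param dwell dwell (equilibration) time per level, min.
#' @param theta_apo apoptotic classification threshold.
#' @return list with `S_on`, `S_off`, `bistable`, `irreversible`, and the
#'   per-level fate tables `up` and `down`.
#' @export
hysteresis_scan <- function(params, S_up_grid = seq(0, 10, by = 0.25),
                            S_down_grid = rev(seq(0, 10, by = 0.25)),
                            dwell = 500, theta_apo = 0.5) {
  stopifnot(inherits(params, "er_params"))
  step_from <- function(state, S) {
    tr <- integrate_protocol(params, constant_stress(S, dwell), state,
                             dt_out = dwell)
    unlist(tr[nrow(tr), -1])
  }
  apo_col <- paste0("APO_", params$n_steps)
  is_apo <- function(state) state[[apo_col]] / params$APO_T > theta_apo

  state <- resting_state(params)
  up_apo <- logical(length(S_up_grid))
  for (i in seq_along(S_up_grid)) {
    state <- step_from(state, S_up_grid[i])
    up_apo[i] <- is_apo(state)
  }
  S_on <- if (any(up_apo)) S_up_grid[which(up_apo)[1]] else NA_real_

  # start the downward scan from a fully engaged death state at high S
  state <- step_from(state, max(S_down_grid))
  down_apo <- logical(length(S_down_grid))
  for (i in seq_along(S_down_grid)) {
    state <- step_from(state, S_down_grid[i])
    down_apo[i] <- is_apo(state)
  }
  still <- which(!down_apo)
  S_off <- if (length(still)) S_down_grid[still[1] - 1] else min(S_down_grid)
  if (!any(down_apo)) S_off <- NA_real_

  irreversible <- isTRUE(down_apo[length(down_apo)]) && min(S_down_grid) == 0
  bistable <- is.na(S_on) && FALSE
  if (!is.na(S_on) && !is.na(S_off)) bistable <- S_off < S_on
  if (!is.na(S_on) && irreversible) bistable <- TRUE

  list(S_on = S_on, S_off = S_off, bistable = bistable,
       irreversible = irreversible,
       up = data.frame(S = S_up_grid, apoptotic = up_apo),
       down = data.frame(S = S_down_grid, apoptotic = down_apo))
}

#' Apoptosis threshold as a function of autophagy activation strength
#'
#' Recomputes [apoptosis_threshold()] for each value of the
#' sensor-dependent autophagy activation constant `kaau_p`: stronger
#' autophagy pushes the death threshold to higher stress levels, weaker
#' autophagy pulls it down.
#'
#' @param params baseline [er_params()].
#' @param kaau_p_grid values of `kaau_p` to scan.
#' @param ... passed to [apoptosis_threshold()].
#' @return data.frame with columns `kaau_p` and `S_star`.
#' @export
threshold_vs_kaau <- function(params, kaau_p_grid = c(0.2, params$kaau_p, 0.7),
                              ...) {
  S_star <- vapply(kaau_p_grid, function(k) {
    apoptosis_threshold(modulate_autophagy(params, k), ...)
  }, numeric(1))
  data.frame(kaau_p = kaau_p_grid, S_star = S_star)
}
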