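#' @useDynLib erfate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

state_names <- function(params) {
  c("ERSS", "AUT", paste0("APO_", seq_len(params$n_steps)))
}

# Build a valid state vector; chain entries default to zero activities.
make_state <- function(params, ERSS = 0, AUT = 0, APO_chain = NULL) {
  if (is.null(APO_chain)) APO_chain <- rep(0, params$n_steps)
  x <- c(ERSS, AUT, APO_chain)
  names(x) <- state_names(params)
  x
}

check_state <- function(state, params, tol = 1e-8) {
  nms <- state_names(params)
  if (is.null(names(state)) || !all(nms %in% names(state))) {
    stop("state must be a named vector with fields: ", paste(nms, collapse = ", "))
  }
  state <- state[nms]
  if (any(!is.finite(state))) {
    stop("non-finite state field: ", paste(nms[!is.finite(state)], collapse = ", "))
  }
  if (state[["ERSS"]] < -tol || state[["ERSS"]] > params$ERSS_T + tol) {
    stop("state field 'ERSS' outside [0, ERSS_T]")
  }
  if (state[["AUT"]] < -tol || state[["AUT"]] > params$AUT_T + tol) {
    stop("state field 'AUT' outside [0, AUT_T]")
  }
  chain <- state[-(1:2)]
  if (any(chain < -tol)) {
    stop("state field '", names(chain)[which(chain < -tol)[1]], "' is negative")
  }
  if (sum(chain) > params$APO_T + tol) {
    stop("state fields 'APO_*' sum above APO_T (chain conservation violated)")
  }
  state
}

#' Time derivatives of the crosstalk network
#'
#' The canonical equations.  Writing `E` for active sensor, `A` for active
#' autophagy inducer, `P_1..P_n` for the modification chain of the
#' apoptosis inducer (with unmodified pool `P_0 = APO_T - sum(P_i)` and
#' fully active form `P_act = P_n`):
#'
#' \deqn{dE/dt = ka_e S (ERSS_T - E) - ki_e E}
#' \deqn{dA/dt = (kaau + kaau' E) (AUT_T - A)/(J_{aa} + AUT_T - A)
#'             - (kiau + kiau' P_{act}) A/(J_{ia} + A)}
#'
#' and for the chain, with per-step forward rate `kf = kaap E` and
#' per-step backward rate
#' `kb = kiap / (1 + k_fb P_act) + kiap' A`:
#' \deqn{dP_i/dt = kf P_{i-1} - kb P_i - [i < n] (kf P_i - kb P_{i+1})}
#'
#' The `kiau' P_act` and `kiap' A` terms are the mutual antagonism; the
#' `1/(1 + k_fb P_act)` factor is the positive feedback on apoptosis
#' deactivation.
#'
#' @param state named numeric state vector (`ERSS`, `AUT`,
#'   `APO_1`..`APO_n`), as produced by [resting_state()] or trajectory
#'   rows.
#' @param S stressor level (single number >= 0).
#' @param params an [er_params()] object.
#' @return named numeric vector of time derivatives (1/min).
#' @export
crosstalk_rhs <- function(state, S, params) {
  stopifnot(inherits(params, "er_params"))
  if (!is.numeric(S) || length(S) != 1L || !is.finite(S) || S < 0) {
    stop("stressor level 'S' must be a single finite number >= 0")
  }
  state <- check_state(state, params)
  drv <- crosstalk_rhs_cpp(as.numeric(state), S, params)
  names(drv) <- names(state)
  drv
}

# Unchecked rhs for integrator hot loop.
rhs_raw <- function(t, y, parms) {
  list(crosstalk_rhs_cpp(y, parms$S, parms$p))
}

#' Integrate the deterministic model under a stress protocol
#'
#' Integrates the ODE system segment by segment (the stressor level is
#' piecewise constant) with `deSolve::lsoda`, relative tolerance `1e-8`
#' and absolute tolerance `1e-10`, and samples the solution on a uniform
#' output grid.  State invariants (bounds and chain conservation) are
#' verified at every output point; a breach beyond `1e-6` raises rather
#' than being silently clipped.
#'
#' @param params an [er_params()] object.
#' @param protocol a [stress_protocol()].
#' @param state0 initial state; defaults to the resting state.
#' @param dt_out output time step (min, > 0).
#' @return a `cell_trajectory`: a data.frame with columns `t`, `ERSS`,
#'   `AUT`, `APO_1..APO_n`, carrying the parameters and protocol as
#'   attributes.
#' @export
integrate_protocol <- function(params, protocol, state0 = NULL, dt_out = 1) {
  stopifnot(inherits(params, "er_params"), inherits(protocol, "stress_protocol"))
  if (dt_out <= 0) stop("dt_out must be > 0")
  if (is.null(state0)) state0 <- resting_state(params)
  y <- check_state(state0, params)

  t_grid <- seq(0, protocol$t_end, by = dt_out)
  if (t_grid[length(t_grid)] < protocol$t_end) t_grid <- c(t_grid, protocol$t_end)
  bounds <- c(protocol$start, protocol$t_end)
  out <- matrix(NA_real_, nrow = length(t_grid), ncol = length(y))
  out[1, ] <- y

  for (seg in seq_along(protocol$level)) {
    t0 <- bounds[seg]; t1 <- bounds[seg + 1]
    keep <- which(t_grid > t0 & t_grid <= t1)
    times <- unique(c(t0, t_grid[keep], t1))
    sol <- deSolve::lsoda(y, times, rhs_raw,
                          parms = list(S = protocol$level[seg], p = params),
                          rtol = 1e-8, atol = 1e-10)
    if (attr(sol, "istate")[1] < 0) {
      stop("integration failed in segment ", seg, "; last valid time ",
           max(sol[, 1]))
    }
    if (length(keep)) {
      out[keep, ] <- sol[match(t_grid[keep], sol[, 1]), -1, drop = FALSE]
    }
    y <- sol[nrow(sol), -1]
  }

  colnames(out) <- state_names(params)
  traj_check_invariants(out, params)
  traj <- data.frame(t = t_grid, out, check.names = FALSE)
  attr(traj, "params") <- params
  attr(traj, "protocol") <- protocol
  class(traj) <- c("cell_trajectory", "data.frame")
  traj
}

traj_check_invariants <- function(mat, params, tol = 1e-6) {
  if (any(mat[, "ERSS"] < -tol) || any(mat[, "ERSS"] > params$ERSS_T + tol)) {
    stop("trajectory violates 0 <= ERSS <= ERSS_T beyond tolerance")
  }
  if (any(mat[, "AUT"] < -tol) || any(mat[, "AUT"] > params$AUT_T + tol)) {
    stop("trajectory violates 0 <= AUT <= AUT_T beyond tolerance")
  }
  chain <- mat[, -(1:2), drop = FALSE]
  if (any(chain < -tol)) stop("trajectory has negative APO chain entries")
  if (any(rowSums(chain) > params$APO_T + tol)) {
    stop("trajectory violates APO chain conservation beyond tolerance")
  }
  invisible(TRUE)
}

#' Resting steady state of the unstressed model
#'
#' Integrates from zero activities at `S = 0` until the maximum absolute
#' derivative falls below `tol` (default `1e-9`/min).
#'
#' @param params an [er_params()] object.
#' @param tol convergence tolerance on the max absolute derivative.
#' @param horizon maximum integration time (min) before giving up.
#' @return named state vector at the resting fixed point.
#' @export
resting_state <- function(params, tol = 1e-9, horizon = 50000) {
  stopifnot(inherits(params, "er_params"))
  y <- make_state(params)
  t_done <- 0
  chunk <- 1000
  repeat {
    sol <- deSolve::lsoda(y, c(0, chunk), rhs_raw,
                          parms = list(S = 0, p = params),
                          rtol = 1e-10, atol = 1e-12)
    y <- sol[nrow(sol), -1]
    t_done <- t_done + chunk
    if (max(abs(crosstalk_rhs_cpp(as.numeric(y), 0, params))) < tol) break
    if (t_done >= horizon) {
      stop("resting state did not converge within ", horizon, " min")
    }
  }
  names(y) <- state_names(params)
  y
}

#' Classify a cell state as apoptotic, autophagic, or neither
#'
#' A cell is apoptotic when the fully active apoptosis-inducer fraction
#' exceeds `theta_apo`, else autophagic when the active autophagy-inducer
#' fraction exceeds `theta_aut`, else neither.  Apoptosis takes precedence
#' (the two fates are mutually exclusive, death winning).
#'
#' @param state a named state vector, or a `cell_trajectory` row set
#'   (data.frame), in which case each row is classified.
#' @param params an [er_params()] object (for the totals and chain length).
#' @param theta_aut,theta_apo classification thresholds, fractions in
#'   (0, 1); defaults 0.5 and 0.5.
#' @return character vector of `"apoptotic"`, `"autophagic"`, `"neither"`.
#' @export
classify <- function(state, params, theta_aut = 0.5, theta_apo = 0.5) {
  stopifnot(inherits(params, "er_params"))
  if (theta_aut <= 0 || theta_aut >= 1 || theta_apo <= 0 || theta_apo >= 1) {
    stop("classification thresholds must lie in (0, 1)")
  }
  apo_col <- paste0("APO_", params$n_steps)
  if (is.data.frame(state)) {
    aut <- state[["AUT"]]; apo <- state[[apo_col]]
  } else {
    aut <- state[["AUT"]]; apo <- state[[apo_col]]
  }
  ifelse(apo / params$APO_T > theta_apo, "apoptotic",
         ifelse(aut / params$AUT_T > theta_aut, "autophagic", "neither"))
}

#' Write a trajectory to CSV
#'
#' Columns `t, ERSS, AUT, APO_1..APO_n, fate`; times in minutes.
#'
#' @param traj a `cell_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  params <- attr(traj, "params")
  df <- as.data.frame(traj)
  df$fate <- classify(df, params)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
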