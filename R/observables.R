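#' Synthetic immunoblot marker time courses from a trajectory
#'
#' Maps a model trajectory (single cell or ensemble mean) onto the four
#' standard wet-lab readouts of the autophagy-apoptosis decision, as
#' band intensities normalised to a loading control:
#'
#' * `LC3II = a * AUT` — lipidated LC3 tracks active autophagy;
#' * `p62 = b * exp(-c * integral(AUT dt))` — p62/SQSTM1 is consumed by
#'   autophagic flux, so its level decays with the cumulative autophagic
#'   activity (a degradation readout, not an instantaneous inverse);
#' * `procaspase3 = d * (APO_T - APO_act)` — the zymogen pool depletes as
#'   the apoptosis inducer activates;
#' * `cleavedPARP = e * APO_act` — cleaved PARP accumulates with active
#'   apoptosis machinery.
#'
#' Multiplicative lognormal measurement noise with coefficient of
#' variation `noise_cv` is applied per band (blot densitometry noise).
#'
#' @param traj a `cell_trajectory` (from [integrate_protocol()],
#'   [simulate_cell()] or [ensemble_mean()]).
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (>= 0; 0 gives deterministic markers).
#' @param seed integer seed for the noise draws.
#' @param scale named list of the proportionality constants
#'   `a, b, c, d, e` (defaults all 1).
#' @return a `marker_timecourse` data.frame with columns `t`, `LC3II`,
#'   `p62`, `procaspase3`, `cleavedPARP`, `loading_control`.
#' @export
markers_from_trajectory <- function(traj, noise_cv = 0, seed = 1,
                                    scale = list(a = 1, b = 1, c = 1,
                                                 d = 1, e = 1)) {
  stopifnot(inherits(traj, "cell_trajectory"))
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  params <- attr(traj, "params")
  apo_col <- paste0("APO_", params$n_steps)
  sc <- utils::modifyList(list(a = 1, b = 1, c = 1, d = 1, e = 1), scale)

  t <- traj$t
  aut <- traj$AUT
  apo <- traj[[apo_col]]
  # cumulative trapezoidal integral of AUT(t)
  n <- length(t)
  cum_aut <- c(0, cumsum(diff(t) * (aut[-1] + aut[-n]) / 2))

  m <- cbind(LC3II = sc$a * aut,
             p62 = sc$b * exp(-sc$c * cum_aut),
             procaspase3 = sc$d * (params$APO_T - apo),
             cleavedPARP = sc$e * apo)
  if (noise_cv > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- matrix(stats::rlnorm(length(m), -sdlog^2 / 2, sdlog), nrow = n)
    m <- m * noise
  }
  out <- data.frame(t = t, m, loading_control = 1)
  attr(out, "noise_cv") <- noise_cv
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("marker_timecourse", "data.frame")
  out
}

#' Annexin-style apoptotic index with counting noise
#'
#' At each requested time, computes the ensemble's true apoptotic fraction
#' and draws the number of scored-apoptotic cells from a binomial with
#' `n_counted` counted cells (the microscopy counting protocol), returning
#' the observed percentage.
#'
#' @param ensemble an `ensemble_result`.
#' @param t_grid times (min) at which the index is scored.
#' @param n_counted number of cells counted per time point (default 1000).
#' @param seed integer seed for the binomial draws.
#' @param theta_aut,theta_apo classification thresholds.
#' @return data.frame with columns `t`, `true_fraction`, `index_percent`.
#' @export
apoptotic_index <- function(ensemble, t_grid, n_counted = 1000, seed = 1,
                            theta_aut = 0.5, theta_apo = 0.5) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  if (n_counted < 1) stop("n_counted must be >= 1")
  true_frac <- vapply(t_grid, function(tt) {
    fate_fractions(ensemble, tt, theta_aut, theta_apo)[["apoptotic"]]
  }, numeric(1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  counted <- stats::rbinom(length(t_grid), n_counted, true_frac)
  data.frame(t = t_grid, true_fraction = true_frac,
             index_percent = 100 * counted / n_counted)
}
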