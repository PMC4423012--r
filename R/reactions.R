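#' The reaction set underlying the stochastic engine
#'
#' Maps every additive rate term of the deterministic model onto exactly
#' one reaction channel.  With `n = n_steps` chain steps there are
#' `4 + 2n` channels: sensor activation/inactivation, autophagy
#' activation/inactivation, and a forward and backward channel per chain
#' step; the conserved unmodified pools (inactive sensor, inactive AUT,
#' unmodified APO) are carried implicitly as complement counts.  Each
#' propensity is `Omega` times the corresponding concentration rate term
#' evaluated at `counts / Omega`, so
#' `colSums(stoichiometry * propensity) / Omega` recovers the
#' deterministic right-hand side at any state — an identity the test suite
#' asserts numerically (see [ssa_drift()]).
#'
#' @param params an [er_params()] object.
#' @return a `reaction_set`: list with `species` (names), `stoich`
#'   (reactions x species integer matrix), `reactions` (channel labels),
#'   and `propensity(counts, S)` returning the channel propensities.
#' @export
to_reactions <- function(params) {
  stopifnot(inherits(params, "er_params"))
  if (params$Omega < 10L) {
    warning("Omega < 10: deep-noise regime outside calibrated behaviour")
  }
  n <- params$n_steps
  species <- state_names(params)
  labels <- c("ERSS_on", "ERSS_off", "AUT_on", "AUT_off",
              as.vector(rbind(paste0("APO_fwd_", seq_len(n)),
                              paste0("APO_bwd_", seq_len(n)))))
  stoich <- matrix(0L, nrow = 4 + 2 * n, ncol = 2 + n,
                   dimnames = list(labels, species))
  stoich[1, 1] <- 1L; stoich[2, 1] <- -1L
  stoich[3, 2] <- 1L; stoich[4, 2] <- -1L
  for (i in seq_len(n)) {
    fwd <- 3 + 2 * i; bwd <- 4 + 2 * i
    stoich[fwd, 2 + i] <- 1L
    if (i > 1) stoich[fwd, 1 + i] <- -1L
    stoich[bwd, 2 + i] <- -1L
    if (i > 1) stoich[bwd, 1 + i] <- 1L
  }
  Omega <- as.numeric(params$Omega)
  structure(list(
    species = species,
    stoich = stoich,
    reactions = labels,
    Omega = Omega,
    propensity = function(counts, S) {
      a <- ssa_propensities_cpp(as.integer(counts), S, params, Omega)
      names(a) <- labels
      a
    }), class = "reaction_set")
}

#' Deterministic drift implied by the reaction set
#'
#' `sum(stoich * propensity) / Omega` at an integer state: by construction
#' this equals [crosstalk_rhs()] evaluated at `counts / Omega`.
#'
#' @param counts integer species counts (`ERSS`, `AUT`, `APO_1..n`).
#' @param S stressor level.
#' @param params an [er_params()] object.
#' @return named numeric drift vector (concentration units per min).
#' @export
ssa_drift <- function(counts, S, params) {
  stopifnot(inherits(params, "er_params"))
  d <- ssa_drift_cpp(as.integer(counts), S, params, as.numeric(params$Omega))
  names(d) <- state_names(params)
  d
}
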