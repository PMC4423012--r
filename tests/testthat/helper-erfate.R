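# Shared fixtures: everything is generated in code at test time.

# Calibrated defaults (the shipped reference set).
p_default <- er_params()

# A cheap valid state for rhs-level tests.
zero_state <- function(p = p_default) {
  x <- c(0, 0, rep(0, p$n_steps))
  names(x) <- c("ERSS", "AUT", paste0("APO_", seq_len(p$n_steps)))
  x
}

# Random valid integer count states for the reaction-set identity checks.
random_count_states <- function(p, n, seed = 1) {
  set.seed(seed)
  NE <- round(p$ERSS_T * p$Omega); NA_ <- round(p$AUT_T * p$Omega)
  NP <- round(p$APO_T * p$Omega)
  lapply(seq_len(n), function(i) {
    chain <- stats::rmultinom(1, NP, rep(1, p$n_steps + 1))[, 1]
    c(sample(0:NE, 1), sample(0:NA_, 1), chain[-1])
  })
}

apo_col <- function(p) paste0("APO_", p$n_steps)
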