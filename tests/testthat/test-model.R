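test_that("rhs at zero activities has only the basal autophagy term", {
  p <- p_default
  d <- crosstalk_rhs(zero_state(p), S = 0, p)
  expect_equal(d[["ERSS"]], 0)
  expect_equal(unname(d[grep("^APO_", names(d))]), rep(0, p$n_steps))
  expect_equal(d[["AUT"]], p$kaau * p$AUT_T / (p$J_aa + p$AUT_T))
  expect_gte(d[["AUT"]], 0)
})

test_that("rhs conserves the apoptosis-inducer pool at arbitrary states", {
  p <- p_default
  set.seed(3)
  for (i in 1:20) {
    chain <- stats::runif(p$n_steps, 0, p$APO_T / p$n_steps)
    st <- c(stats::runif(1, 0, p$ERSS_T), stats::runif(1, 0, p$AUT_T), chain)
    names(st) <- names(zero_state(p))
    d <- crosstalk_rhs(st, S = stats::runif(1, 0, 10), p)
    # the unmodified pool's implied derivative balances the chain exactly
    kf <- p$kaap * st[["ERSS"]]
    kb <- p$kiap / (1 + p$k_fb * chain[p$n_steps]) + p$kiap_p * st[["AUT"]]
    pool <- p$APO_T - sum(chain)
    d_pool <- -(kf * pool - kb * chain[1])
    expect_equal(sum(d[grep("^APO_", names(d))]) + d_pool, 0, tolerance = 1e-12)
  }
})

test_that("rhs rejects malformed input naming the offending field", {
  p <- p_default
  expect_error(crosstalk_rhs(zero_state(p), S = -1, p), "'S'")
  bad <- zero_state(p); bad[["AUT"]] <- p$AUT_T + 1
  expect_error(crosstalk_rhs(bad, S = 1, p), "AUT")
  bad <- zero_state(p); bad[[apo_col(p)]] <- -0.5
  expect_error(crosstalk_rhs(bad, S = 1, p), "APO")
})

test_that("the resting state is a stable fixed point below the apoptotic threshold", {
  p <- p_default
  rest <- resting_state(p)
  expect_lt(rest[[apo_col(p)]] / p$APO_T, 0.05)
  expect_lt(max(abs(crosstalk_rhs(rest, 0, p))), 1e-8)
  expect_equal(classify(rest, p), "neither")

  # constancy under a null protocol
  tr <- integrate_protocol(p, constant_stress(0, 100), rest, dt_out = 10)
  expect_lt(max(abs(as.matrix(tr[, -1]) -
                    matrix(rest, nrow(tr), length(rest), byrow = TRUE))), 1e-5)

  # local stability: a small autophagy perturbation decays back
  pert <- rest
  pert[["AUT"]] <- rest[["AUT"]] * 1.01
  tr2 <- integrate_protocol(p, constant_stress(0, 2000), pert, dt_out = 2000)
  expect_equal(unlist(tr2[nrow(tr2), -1]), rest,
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("integration error control: tightening tolerances moves endpoints < 1e-6", {
  p <- p_default
  prot <- constant_stress(5, 240)
  rest <- resting_state(p)
  end1 <- unlist(integrate_protocol(p, prot, rest, dt_out = 240)[2, -1])
  # independent re-integration on a fine grid (many internal restarts)
  end2 <- unlist(integrate_protocol(p, prot, rest, dt_out = 0.5)[481, -1])
  expect_lt(max(abs(end1 - end2)), 1e-6)
})

test_that("trajectories satisfy bounds and chain conservation on the grid", {
  p <- p_default
  for (S in c(1, 5, 10)) {
    tr <- integrate_protocol(p, constant_stress(S, 240), dt_out = 5)
    expect_true(all(tr$ERSS >= -1e-8 & tr$ERSS <= p$ERSS_T + 1e-8))
    expect_true(all(tr$AUT >= -1e-8 & tr$AUT <= p$AUT_T + 1e-8))
    chain <- as.matrix(tr[, grep("^APO_", names(tr)), drop = FALSE])
    expect_true(all(chain >= -1e-8))
    expect_true(all(rowSums(chain) <= p$APO_T + 1e-6))
  }
})

test_that("steady-state sensor activity is nondecreasing in stress level", {
  p <- p_default
  erss <- vapply(0:10, function(S) {
    p$ka_e * S * p$ERSS_T / (p$ka_e * S + p$ki_e)
  }, numeric(1))
  expect_true(all(diff(erss) >= 0))
  # and the integrated model agrees at a long horizon
  tr <- vapply(c(0, 3, 10), function(S) {
    integrate_protocol(p, constant_stress(S, 2000), dt_out = 2000)[2, "ERSS"]
  }, numeric(1))
  expect_true(all(diff(tr) > 0))
})

test_that("mutual antagonism has the documented sign structure", {
  p <- p_default
  set.seed(4)
  eps <- 1e-6
  for (i in 1:10) {
    chain <- stats::runif(p$n_steps, 0, p$APO_T / (p$n_steps + 1))
    st <- c(stats::runif(1, 0, 1), stats::runif(1, 0.1, 0.9), chain)
    names(st) <- names(zero_state(p))
    S <- stats::runif(1, 0, 10)
    d0 <- crosstalk_rhs(st, S, p)
    up_apo <- st; up_apo[[apo_col(p)]] <- up_apo[[apo_col(p)]] + eps
    d1 <- crosstalk_rhs(up_apo, S, p)
    expect_lte((d1[["AUT"]] - d0[["AUT"]]) / eps, 1e-8)
    up_aut <- st; up_aut[["AUT"]] <- up_aut[["AUT"]] + eps
    d2 <- crosstalk_rhs(up_aut, S, p)
    expect_lte((d2[[apo_col(p)]] - d0[[apo_col(p)]]) / eps, 1e-8)
  }
})

test_that("classification applies thresholds with apoptosis precedence", {
  p <- p_default
  st <- zero_state(p)
  st[["AUT"]] <- 0.8 * p$AUT_T; st[[apo_col(p)]] <- 0.1 * p$APO_T
  expect_equal(classify(st, p), "autophagic")
  st[[apo_col(p)]] <- 0.8 * p$APO_T
  expect_equal(classify(st, p), "apoptotic")
  expect_equal(classify(zero_state(p), p), "neither")
  expect_error(classify(st, p, theta_aut = 0), "thresholds")
})

test_that("trajectory CSV export carries the documented columns", {
  p <- p_default
  tr <- integrate_protocol(p, constant_stress(1, 20), dt_out = 10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  got <- utils::read.csv(f)
  expect_equal(names(got),
               c("t", "ERSS", "AUT", paste0("APO_", seq_len(p$n_steps)), "fate"))
  expect_equal(nrow(got), nrow(tr))
})
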