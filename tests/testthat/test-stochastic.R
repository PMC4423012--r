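test_that("the SSA is reproducible under seed and sensitive to it", {
  p <- p_default
  prot <- constant_stress(5, 60)
  tr1 <- simulate_cell(p, prot, seed = 42, dt_out = 2)
  tr2 <- simulate_cell(p, prot, seed = 42, dt_out = 2)
  tr3 <- simulate_cell(p, prot, seed = 43, dt_out = 2)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  expect_false(identical(as.data.frame(tr1), as.data.frame(tr3)))
})

test_that("molecule counts stay on the lattice and conserve pools", {
  p <- p_default
  tr <- simulate_cell(p, constant_stress(8, 120), seed = 7, dt_out = 1)
  counts <- as.matrix(tr[, -1]) * p$Omega
  expect_true(all(abs(counts - round(counts)) < 1e-9))
  expect_true(all(counts >= 0))
  chain <- counts[, grep("^APO_", colnames(counts)), drop = FALSE]
  expect_true(all(rowSums(chain) <= round(p$APO_T * p$Omega)))
  expect_true(all(counts[, "ERSS"] <= round(p$ERSS_T * p$Omega)))
  expect_true(all(counts[, "AUT"] <= round(p$AUT_T * p$Omega)))
})

test_that("an ensemble is bit-identical under its master seed", {
  p <- p_default
  e1 <- simulate_ensemble(p, constant_stress(5, 40), n_cells = 4,
                          master_seed = 99, dt_out = 4)
  e2 <- simulate_ensemble(p, constant_stress(5, 40), n_cells = 4,
                          master_seed = 99, dt_out = 4)
  expect_identical(lapply(e1$trajectories, as.data.frame),
                   lapply(e2$trajectories, as.data.frame))
  expect_identical(e1$fate, e2$fate)
  expect_identical(e1$seeds, e2$seeds)
})

test_that("a single-cell ensemble reduces to simulate_cell", {
  p <- p_default
  ens <- simulate_ensemble(p, constant_stress(3, 40), n_cells = 1,
                           master_seed = 5, dt_out = 4)
  tr <- simulate_cell(p, constant_stress(3, 40), seed = ens$seeds[1], dt_out = 4)
  expect_identical(as.data.frame(ens$trajectories[[1]]), as.data.frame(tr))
})

test_that("ensemble means converge to the deterministic solution as Omega grows", {
  # law of large numbers / system-size expansion: the sup-norm deviation of
  # the ensemble mean from the ODE solution shrinks with Omega.  This is a
  # property of the intrinsic noise, so extrinsic stress variability is off.
  p <- unclass(p_default); p$sigma_S <- 0; class(p) <- "er_params"
  prot <- constant_stress(1, 120)
  det <- integrate_protocol(p, prot, dt_out = 10)
  dev <- vapply(c(100L, 2000L), function(om) {
    pom <- unclass(p); pom$Omega <- om; class(pom) <- "er_params"
    ens <- simulate_ensemble(pom, prot, n_cells = 10, master_seed = 17,
                             dt_out = 10)
    m <- ensemble_mean(ens)
    max(abs(m$AUT - det$AUT))
  }, numeric(1))
  expect_lt(dev[2], dev[1])
  expect_lt(dev[2], 0.05 * p$AUT_T)
})

test_that("extrinsic stress variability is seeded and mean-one on the log scale", {
  p <- p_default
  expect_gt(p$sigma_S, 0)   # calibrated default includes extrinsic noise
  tr_a <- simulate_cell(p, constant_stress(5, 30), seed = 1, dt_out = 5)
  tr_b <- simulate_cell(p, constant_stress(5, 30), seed = 1, dt_out = 5)
  expect_identical(as.data.frame(tr_a), as.data.frame(tr_b))
  # the lognormal factor is mean-one: E[S_eff] = S0
  set.seed(1)
  draws <- exp(stats::rnorm(2e4, -p$sigma_S^2 / 2, p$sigma_S))
  expect_equal(mean(draws), 1, tolerance = 0.01)
})
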