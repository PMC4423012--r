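test_that("noise-free markers are deterministic functions of the trajectory", {
  p <- p_default
  rest <- resting_state(p)
  tr <- integrate_protocol(p, constant_stress(0, 60), rest, dt_out = 10)
  mk <- markers_from_trajectory(tr, noise_cv = 0)
  # resting cell: flat markers, essentially no PARP cleavage
  expect_lt(max(mk$cleavedPARP), 0.05)
  expect_lt(diff(range(mk$LC3II)), 1e-3)
  expect_equal(mk$procaspase3, p$APO_T - tr[[apo_col(p)]])
  # p62 decays with cumulative autophagic flux, so it is nonincreasing
  expect_true(all(diff(mk$p62) <= 1e-12))
})

test_that("under high stress PARP cleavage follows the autophagy transient", {
  p <- p_default
  tr <- integrate_protocol(p, constant_stress(8, 240), dt_out = 2)
  mk <- markers_from_trajectory(tr, noise_cv = 0)
  t_peak_aut <- mk$t[which.max(mk$LC3II)]
  t_parp <- mk$t[which(mk$cleavedPARP > 0.5 * max(mk$cleavedPARP))[1]]
  expect_lt(t_peak_aut, t_parp)
})

test_that("marker noise is seeded and has the configured dispersion", {
  p <- p_default
  tr <- integrate_protocol(p, constant_stress(1, 60), dt_out = 30)
  m1 <- markers_from_trajectory(tr, noise_cv = 0.2, seed = 1)
  m2 <- markers_from_trajectory(tr, noise_cv = 0.2, seed = 1)
  m3 <- markers_from_trajectory(tr, noise_cv = 0.2, seed = 2)
  expect_identical(m1, m2)
  expect_false(identical(m1, m3))

  # estimated CV of log-intensities over many draws within 20% of nominal
  base <- markers_from_trajectory(tr, noise_cv = 0)$LC3II[2]
  draws <- vapply(1:1000, function(s) {
    markers_from_trajectory(tr, noise_cv = 0.2, seed = s)$LC3II[2]
  }, numeric(1))
  cv_hat <- stats::sd(draws) / mean(draws)
  expect_lt(abs(cv_hat - 0.2) / 0.2, 0.2)
  expect_equal(mean(draws), base, tolerance = 0.05)
})

test_that("the apoptotic index has binomial counting noise around the truth", {
  p <- p_default
  ens <- simulate_ensemble(p, constant_stress(0, 30), n_cells = 5,
                           master_seed = 4, dt_out = 5)
  idx <- apoptotic_index(ens, c(0, 30), n_counted = 500, seed = 1)
  expect_equal(idx$index_percent, c(0, 0))   # true fraction zero

  ens5 <- simulate_ensemble(p, constant_stress(6, 200), n_cells = 10,
                            master_seed = 14, dt_out = 10)
  truth <- fate_fractions(ens5, 200)[["apoptotic"]]
  big <- apoptotic_index(ens5, 200, n_counted = 2e5, seed = 2)
  expect_equal(big$index_percent / 100, truth, tolerance = 0.02)
})
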