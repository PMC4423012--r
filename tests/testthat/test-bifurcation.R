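test_that("the threshold bisection brackets the fate change", {
  p <- p_default
  s_star <- apoptosis_threshold(p, resolution = 0.05)
  expect_true(is.finite(s_star))
  rest <- resting_state(p)
  below <- integrate_protocol(p, constant_stress(s_star - 0.1, 240), rest,
                              dt_out = 240)
  above <- integrate_protocol(p, constant_stress(s_star + 0.05, 240), rest,
                              dt_out = 240)
  expect_false(classify(below[2, ], p) == "apoptotic")
  expect_equal(classify(above[2, ], p), "apoptotic")
})

test_that("the apoptosis threshold responds monotonically to autophagy strength", {
  p <- p_default
  thr <- threshold_vs_kaau(p, c(0.2, p$kaau_p, 0.7), resolution = 0.05)
  expect_true(all(is.finite(thr$S_star)))
  expect_lt(thr$S_star[1], thr$S_star[2])   # weaker autophagy: lower threshold
  expect_lt(thr$S_star[2], thr$S_star[3])   # stronger autophagy: higher threshold
})

test_that("the threshold is autophagy-independent when the crosstalk is cut", {
  p <- unclass(p_default)
  p$kiau_p <- 0; p$kiap_p <- 0    # no mutual antagonism
  class(p) <- "er_params"
  thr <- threshold_vs_kaau(p, c(0.2, 0.45, 0.7), resolution = 0.1)
  expect_true(all(is.na(thr$S_star)) || max(thr$S_star) - min(thr$S_star) < 0.11)
})

test_that("hysteresis scan on defaults reports bistability and a persistent death state", {
  p <- p_default
  hys <- hysteresis_scan(p, S_up_grid = seq(0, 10, by = 0.5),
                         S_down_grid = rev(seq(0, 10, by = 0.5)))
  expect_true(is.finite(hys$S_on))
  expect_true(hys$bistable)
  expect_true(hys$irreversible)
  expect_true(is.na(hys$S_off) || hys$S_off < hys$S_on)
})

test_that("a one-step chain without feedback is graded and monostable", {
  p0 <- p_default
  suppressWarnings(p1 <- er_params(
    ka_e = p0$ka_e, ki_e = p0$ki_e, kaau = p0$kaau, kaau_p = p0$kaau_p,
    J_aa = p0$J_aa, J_ia = p0$J_ia, kiau = p0$kiau, kiau_p = p0$kiau_p,
    kaap = p0$kaap, kiap = p0$kiap, kiap_p = p0$kiap_p,
    n_steps = 1, k_fb = 0))
  hys <- hysteresis_scan(p1, S_up_grid = seq(0, 10, by = 1),
                         S_down_grid = rev(seq(0, 10, by = 1)))
  expect_false(hys$irreversible)
  expect_false(hys$bistable)
  # steady-state activation is graded: no jump larger than half the pool
  rest <- resting_state(p1)
  apo <- vapply(seq(0, 10, by = 1), function(S) {
    tr <- integrate_protocol(p1, constant_stress(S, 1500), rest, dt_out = 1500)
    tr[2, "APO_1"]
  }, numeric(1))
  expect_true(all(diff(apo) >= -1e-6))
  expect_lt(max(diff(apo)), 0.5 * p1$APO_T)
})
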