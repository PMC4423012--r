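test_that("calibration is reproducible under its master seed", {
  # deterministic anchors only (a1, a4) keep this cheap
  anchors <- anchor_set()[c("a1", "a4")]
  class(anchors) <- "anchor_set"
  ss <- list(kaap = c(0.1, 0.4))
  fit1 <- suppressWarnings(calibrate(ss, anchors, master_seed = 3, budget = 4,
                                     refine = 1))
  fit2 <- suppressWarnings(calibrate(ss, anchors, master_seed = 3, budget = 4,
                                     refine = 1))
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$trace, fit2$trace)
})

test_that("reported residuals match an independent re-evaluation", {
  anchors <- anchor_set()[c("a1", "a4")]
  class(anchors) <- "anchor_set"
  fit <- suppressWarnings(calibrate(list(kaap = c(0.1, 0.4)), anchors,
                                    master_seed = 3, budget = 3, refine = 0))
  re <- vapply(anchors, function(a) a$residual(fit$params, 3L + 77L), numeric(1))
  expect_equal(unname(fit$residuals), unname(re))
})

test_that("restricting to the threshold anchor returns a window-satisfying set", {
  a1 <- anchor_set()["a1"]
  class(a1) <- "anchor_set"
  fit <- suppressWarnings(calibrate(list(kaap = c(0.05, 0.6)), a1,
                                    master_seed = 9, budget = 6, refine = 1))
  s <- apoptosis_threshold(fit$params, resolution = 0.05)
  expect_true(is.finite(s) && s > 3 && s < 5)
})

test_that("the shipped default parameters satisfy the full anchor set", {
  anchors <- anchor_set(n_cells = 20)
  res <- anchor_residuals(er_params(), anchors, seed = 78L)
  w <- vapply(anchors, function(a) a$weight, numeric(1))
  expect_true(all(res[is.infinite(w)] == 0))
  expect_lt(sum(res[is.finite(w)]), 0.5)
})

test_that("calibration rejects unknown search dimensions", {
  expect_error(calibrate(list(bogus = c(0, 1)), anchor_set()), "bogus")
})
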