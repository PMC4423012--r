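test_that("fate fractions of an unstressed ensemble are all 'neither'", {
  p <- p_default
  ens <- simulate_ensemble(p, constant_stress(0, 30), n_cells = 6,
                           master_seed = 3, dt_out = 5)
  f <- fate_fractions(ens)
  expect_equal(unname(f), c(0, 0, 1))
  expect_equal(sum(f), 1)
})

test_that("fate fractions match a brute-force recount of stored trajectories", {
  p <- p_default
  ens <- simulate_ensemble(p, constant_stress(5, 120), n_cells = 12,
                           master_seed = 8, dt_out = 4)
  for (t_eval in c(60, 120)) {
    f <- fate_fractions(ens, t_eval)
    manual <- table(factor(vapply(ens$trajectories, function(tr) {
      row <- tr[tr$t == t_eval, ]
      apo <- row[[apo_col(p)]] / p$APO_T
      aut <- row$AUT / p$AUT_T
      if (apo > 0.5) "apoptotic" else if (aut > 0.5) "autophagic" else "neither"
    }, character(1)), levels = c("autophagic", "apoptotic", "neither"))) / 12
    expect_equal(unname(f), as.numeric(manual))
  }
  expect_error(fate_fractions(ens, 500), "horizon")
})

test_that("activation times recompute from the stored trajectories", {
  p <- p_default
  ens <- simulate_ensemble(p, constant_stress(8, 180), n_cells = 10,
                           master_seed = 12, dt_out = 2)
  atd <- activation_time_distribution(ens)
  expect_equal(nrow(atd), 10)
  for (i in seq_len(10)) {
    tr <- ens$trajectories[[i]]
    hit <- which(tr[[apo_col(p)]] / p$APO_T > 0.5)
    if (length(hit)) {
      expect_false(atd$censored[i])
      expect_equal(atd$time[i], tr$t[hit[1]])
    } else {
      expect_true(atd$censored[i])
      expect_equal(atd$time[i], 180)
    }
  }
})

test_that("ensemble_mean equals the arithmetic mean of the raw trajectories", {
  p <- p_default
  ens <- simulate_ensemble(p, constant_stress(4, 40), n_cells = 5,
                           master_seed = 21, dt_out = 8)
  m <- ensemble_mean(ens)
  manual <- Reduce(`+`, lapply(ens$trajectories, function(tr) tr$AUT)) / 5
  expect_equal(m$AUT, manual)
  # a single-cell ensemble averages to itself
  e1 <- simulate_ensemble(p, constant_stress(4, 40), n_cells = 1,
                          master_seed = 21, dt_out = 8)
  expect_equal(as.data.frame(ensemble_mean(e1)),
               as.data.frame(e1$trajectories[[1]]), ignore_attr = TRUE)
})

test_that("fate curves keep fractions summing to one and write CSV + sidecar", {
  p <- p_default
  curve <- dose_response_scan(p, S_grid = c(1, 5), n_cells = 8, t_end = 60,
                              t_eval = 60, master_seed = 2, dt_out = 6)
  expect_equal(curve$frac_autophagic + curve$frac_apoptotic + curve$frac_neither,
               rep(1, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_fate_curve(curve, f)
  got <- utils::read.csv(f)
  expect_equal(names(got), c("sweep_value", "frac_autophagic", "frac_apoptotic",
                             "frac_neither", "n_cells", "seed"))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$sweep, "S0")
  expect_equal(side$n_cells, 8L)
})

test_that("a grid of length one reduces to fate_fractions", {
  p <- p_default
  curve <- dose_response_scan(p, S_grid = 5, n_cells = 6, t_end = 60,
                              t_eval = 60, master_seed = 31, dt_out = 6)
  sub_seed <- spawn_seeds(31 + 1L, 1)
  ens <- simulate_ensemble(p, constant_stress(5, 60), 6, sub_seed, dt_out = 6)
  f <- fate_fractions(ens, 60)
  expect_equal(c(curve$frac_autophagic, curve$frac_apoptotic, curve$frac_neither),
               unname(f))
})

test_that("doubling the ensemble roughly halves the squared standard error", {
  # Monte-Carlo scaling: the apoptotic-fraction estimator behaves like a
  # binomial mean, so the SE at 2n is within 3x of the theoretical
  # sqrt(1/2) shrinkage of the SE at n
  p <- p_default
  frac_at <- function(n, seed) {
    ens <- simulate_ensemble(p, constant_stress(5, 120), n, seed, dt_out = 6)
    fate_fractions(ens)[["apoptotic"]]
  }
  f_small <- vapply(1:8, function(i) frac_at(10, 1000 + i), numeric(1))
  f_big <- vapply(1:8, function(i) frac_at(20, 2000 + i), numeric(1))
  se_small <- stats::sd(f_small); se_big <- stats::sd(f_big)
  expect_lt(se_big, 3 * se_small / sqrt(2) + 1e-9)
})
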