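#' Behavioural anchors for parameter calibration
#'
#' The model's free kinetic constants are not identifiable from first
#' principles; they are pinned by a small set of behavioural anchors
#' describing the simulated phenotypes the model must reproduce:
#'
#' * `a1` (hard): the deterministic apoptosis threshold at 240 min lies
#'   strictly between stress levels 3 and 5.
#' * `a2` (hard): in 240-min stochastic ensembles, the apoptotic fraction
#'   stays below 0.5 at `S0 = 1` and `S0 = 2` and exceeds 0.5 for
#'   `S0 >= 5`.
#' * `a3`: under washout of `S0 = 10` evaluated 120 min post-washout, the
#'   apoptotic fraction is low (< 0.2) for washout at 15-30 min, rises
#'   through the 30-90 min window, and is about 0.95 at 105 min.
#' * `a4` (hard): at `S0 = 5` the autophagy inducer peaks transiently
#'   before the apoptosis inducer activates.
#'
#' Each anchor is evaluated with fixed sub-seeds (common random numbers)
#' so that candidate parameter sets are compared on identical noise
#' realisations.
#'
#' @param n_cells ensemble size used for the stochastic anchors (smaller
#'   values make calibration cheaper at the cost of noisier residuals).
#' @return an `anchor_set`: list of anchor records with fields `id`,
#'   `weight` (`Inf` marks a hard anchor), and `residual(params, seed)`
#'   returning 0 when satisfied and a positive deviation otherwise.
#' @export
anchor_set <- function(n_cells = 30) {
  a1 <- list(id = "a1", weight = Inf, residual = function(params, seed) {
    s <- apoptosis_threshold(params, resolution = 0.05)
    if (is.na(s)) return(2)
    max(0, 3 - s, s - 5) / 1
  })
  a2 <- list(id = "a2", weight = Inf, residual = function(params, seed) {
    dev <- 0
    for (S0 in c(1, 2, 5, 6, 8, 10)) {
      ens <- simulate_ensemble(params, constant_stress(S0, 240), n_cells,
                               seed + S0, dt_out = 4)
      f <- fate_fractions(ens)[["apoptotic"]]
      dev <- dev + if (S0 <= 2) max(0, f - 0.5) else max(0, 0.5 - f)
    }
    dev
  })
  a3 <- list(id = "a3", weight = 1, residual = function(params, seed) {
    wc <- washout_commitment_curve(params, n_cells = n_cells,
                                   master_seed = seed, dt_out = 4)
    f <- wc$frac_apoptotic
    max(0, f[1] - 0.2) + max(0, f[2] - 0.35) +
      abs(f[7] - 0.95) + max(0, f[4] - f[6])
  })
  a4 <- list(id = "a4", weight = Inf, residual = function(params, seed) {
    tr <- integrate_protocol(params, constant_stress(5, 240), dt_out = 2)
    apo <- tr[[paste0("APO_", params$n_steps)]]
    peak_aut <- tr$t[which.max(tr$AUT)]
    cross <- which(apo / params$APO_T > 0.5)
    t_apo <- if (length(cross)) tr$t[cross[1]] else 240
    max(0, (peak_aut - t_apo) / 240)
  })
  structure(list(a1 = a1, a2 = a2, a3 = a3, a4 = a4), class = "anchor_set")
}

anchor_residuals <- function(params, anchors, seed) {
  vapply(anchors, function(a) a$residual(params, seed), numeric(1))
}

#' Calibrate free parameters against the behavioural anchors
#'
#' Coarse Latin-hypercube-style random search over the given bounds,
#' followed by greedy local refinement of the best candidate (coordinate
#' steps, shrinking multiplicatively).  All stochastic anchors are
#' evaluated with the same fixed sub-seeds for every candidate (common
#' random numbers), so the search minimises a deterministic function of
#' the parameters and is exactly reproducible under `master_seed`.
#'
#' The total penalty is the weighted sum of anchor residuals, with hard
#' anchors (weight `Inf`) counted at a large finite factor so that no
#' soft-anchor improvement can outbid a hard-anchor violation.
#'
#' @param search_space named list of `c(lower, upper)` bounds for a subset
#'   of [er_params()] fields (typically `kaap`, `kiap`, `kiap_p`,
#'   `kiau_p`, `k_fb`, `ka_e`, `ki_e`).
#' @param anchors an [anchor_set()].
#' @param master_seed integer; governs both the candidate sampling and
#'   the common-random-number sub-seeds.
#' @param budget number of coarse candidates to evaluate.
#' @param base baseline [er_params()] supplying the fields not searched.
#' @param refine number of local refinement sweeps.
#' @return list with `params` (best `er_params`), `residuals` (per-anchor
#'   deviations of the best candidate), `penalty`, `ok` (all hard anchors
#'   satisfied), and `trace` (data.frame of evaluated candidates).
#' @export
calibrate <- function(search_space, anchors = anchor_set(),
                      master_seed = 1, budget = 40, base = er_params(),
                      refine = 2) {
  stopifnot(is.list(search_space), length(search_space) >= 1)
  nm <- names(search_space)
  bad <- setdiff(nm, names(unclass(base)))
  if (length(bad)) stop("unknown parameter(s) in search_space: ",
                        paste(bad, collapse = ", "))
  hard_factor <- 1e4
  w <- vapply(anchors, function(a) a$weight, numeric(1))
  w_eff <- ifelse(is.infinite(w), hard_factor, w)
  crn_seed <- as.integer(master_seed) + 77L

  penalty_of <- function(theta) {
    p <- unclass(base)
    for (k in nm) p[[k]] <- theta[[k]]
    p <- tryCatch({ validate_er_params(p); class(p) <- "er_params"; p },
                  error = function(e) NULL)
    if (is.null(p)) return(list(pen = Inf, res = rep(NA_real_, length(anchors))))
    res <- tryCatch(anchor_residuals(p, anchors, crn_seed),
                    error = function(e) rep(Inf, length(anchors)))
    list(pen = sum(w_eff * res), res = res)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(master_seed))
  # stratified (Latin hypercube) coarse sample
  u <- vapply(seq_along(nm), function(j) (sample(budget) - stats::runif(budget)) / budget,
              numeric(budget))
  lower <- vapply(search_space, `[`, numeric(1), 1)
  upper <- vapply(search_space, `[`, numeric(1), 2)
  cand <- sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
  colnames(cand) <- nm

  trace <- data.frame()
  best <- NULL
  for (i in seq_len(budget)) {
    theta <- as.list(cand[i, ])
    ev <- penalty_of(theta)
    trace <- rbind(trace, data.frame(as.list(cand[i, ]), penalty = ev$pen))
    if (is.null(best) || ev$pen < best$pen) best <- list(theta = theta, pen = ev$pen, res = ev$res)
  }

  step <- 0.25
  for (sweep_i in seq_len(refine)) {
    for (k in nm) {
      for (dir in c(1 - step, 1 + step)) {
        theta <- best$theta
        theta[[k]] <- min(max(theta[[k]] * dir, lower[[k]]), upper[[k]])
        ev <- penalty_of(theta)
        if (ev$pen < best$pen) best <- list(theta = theta, pen = ev$pen, res = ev$res)
      }
    }
    step <- step / 2
  }

  p <- unclass(base)
  for (k in nm) p[[k]] <- best$theta[[k]]
  class(p) <- "er_params"
  res <- anchor_residuals(p, anchors, crn_seed)
  names(res) <- names(anchors)
  ok <- all(res[is.infinite(w)] == 0)
  if (!ok) {
    warning("calibration did not satisfy all hard anchors: ",
            paste(names(res)[is.infinite(w) & res > 0], collapse = ", "))
  }
  list(params = p, residuals = res, penalty = best$pen, ok = ok, trace = trace)
}
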