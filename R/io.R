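#' Run a named simulation scenario from a configuration
#'
#' One entry point for the package's standard pipelines.  The
#' configuration is a named list (or path to a YAML file) with at least a
#' `scenario` key; every run is governed by a single master `seed`,
#' echoed together with the parameter hash into a JSON sidecar next to
#' each output file.
#'
#' Scenarios and their specific keys:
#' * `"single-cell"`: one stochastic cell; `S0`, `t_end`.
#' * `"ensemble"`: `S0`, `t_end`, `n_cells`.
#' * `"dose-response"`: `S_grid` (default 1:10), `n_cells`, `t_end`.
#' * `"washout"`: `S0` (default 10), `washout_grid`, `t_post`, `n_cells`.
#' * `"modulate"`: dose-response under a modified `kaau_p` (`kaau_p_new`).
#' * `"bifurcation"`: threshold and hysteresis characterisation.
#' * `"calibrate"`: anchor-based calibration over `search_space`.
#' * `"observables"`: synthetic markers + apoptotic index for an
#'   ensemble; `S0`, `t_end`, `n_cells`, `noise_cv`.
#'
#' Common keys: `params` (path to a YAML parameter file, defaults to the
#' shipped calibrated set), `seed` (default 1), `out` (output directory,
#' created if missing), `n_cells` (default 50), `omega` (overrides the
#' parameter file's system size).
#'
#' @param config named list or path to a YAML config file.
#' @return (invisibly) a character vector of the files written.
#' @export
run_scenario <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  need <- function(key, default = NULL) {
    if (!is.null(config[[key]])) return(config[[key]])
    if (is.null(default)) stop("missing config key: '", key, "'")
    default
  }
  scenario <- need("scenario")
  out_dir <- need("out", "results")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(need("seed", 1L))
  params <- if (!is.null(config$params)) read_params(config$params)
            else read_params(default_params_file())
  if (!is.null(config$omega)) {
    p <- unclass(params); p$Omega <- as.integer(config$omega)
    validate_er_params(p); class(p) <- "er_params"; params <- p
  }
  n_cells <- as.integer(need("n_cells", 50L))

  sidecar <- function(path, extra = list()) {
    info <- c(list(scenario = scenario, seed = seed,
                   params_hash = params_hash(params),
                   package_version = as.character(utils::packageVersion("erfate"))),
              extra)
    jsonlite::write_json(info, paste0(path, ".json"), auto_unbox = TRUE)
    paste0(path, ".json")
  }
  written <- character()
  add <- function(...) written <<- c(written, ...)

  if (scenario == "single-cell") {
    tr <- simulate_cell(params, constant_stress(need("S0", 5), need("t_end", 240)),
                        seed = seed)
    f <- file.path(out_dir, "single_cell.csv")
    write_trajectory(tr, f); add(f, sidecar(f))
  } else if (scenario == "ensemble") {
    ens <- simulate_ensemble(params, constant_stress(need("S0", 5), need("t_end", 240)),
                             n_cells, seed)
    f <- file.path(out_dir, "ensemble_mean.csv")
    write_trajectory(ensemble_mean(ens), f)
    f2 <- file.path(out_dir, "activation_times.csv")
    utils::write.csv(activation_time_distribution(ens), f2, row.names = FALSE)
    add(f, f2, sidecar(f))
  } else if (scenario == "dose-response") {
    curve <- dose_response_scan(params, need("S_grid", 1:10), n_cells,
                                need("t_end", 240), need("t_end", 240), seed)
    f <- file.path(out_dir, "dose_response.csv")
    write_fate_curve(curve, f); add(f, paste0(f, ".json"))
  } else if (scenario == "washout") {
    curve <- washout_commitment_curve(params, need("S0", 10),
                                      need("washout_grid", seq(15, 105, 15)),
                                      need("t_post", 120), n_cells, seed)
    f <- file.path(out_dir, "washout_commitment.csv")
    write_fate_curve(curve, f); add(f, paste0(f, ".json"))
  } else if (scenario == "modulate") {
    p2 <- modulate_autophagy(params, need("kaau_p_new"))
    curve <- dose_response_scan(p2, need("S_grid", 1:10), n_cells,
                                need("t_end", 240), need("t_end", 240), seed)
    f <- file.path(out_dir, "modulated_dose_response.csv")
    write_fate_curve(curve, f); add(f, paste0(f, ".json"))
  } else if (scenario == "bifurcation") {
    thr <- threshold_vs_kaau(params)
    hys <- hysteresis_scan(params)
    f <- file.path(out_dir, "threshold_vs_kaau.csv")
    utils::write.csv(thr, f, row.names = FALSE)
    f2 <- file.path(out_dir, "hysteresis.csv")
    utils::write.csv(rbind(cbind(scan = "up", hys$up),
                           cbind(scan = "down", hys$down)), f2, row.names = FALSE)
    add(f, f2, sidecar(f, list(S_on = hys$S_on, S_off = hys$S_off,
                               bistable = hys$bistable,
                               irreversible = hys$irreversible)))
  } else if (scenario == "calibrate") {
    ss <- lapply(need("search_space"), as.numeric)
    fit <- calibrate(ss, master_seed = seed, base = params,
                     budget = as.integer(need("budget", 40L)))
    f <- file.path(out_dir, "calibrated_params.yaml")
    write_params(fit$params, f)
    add(f, sidecar(f, list(penalty = fit$penalty, ok = fit$ok,
                           residuals = as.list(fit$residuals))))
  } else if (scenario == "observables") {
    ens <- simulate_ensemble(params, constant_stress(need("S0", 5), need("t_end", 240)),
                             n_cells, seed)
    mk <- markers_from_trajectory(ensemble_mean(ens),
                                  noise_cv = need("noise_cv", 0.1), seed = seed)
    f <- file.path(out_dir, "markers.csv")
    utils::write.csv(as.data.frame(mk), f, row.names = FALSE)
    idx <- apoptotic_index(ens, seq(0, ens$protocol$t_end, by = 30), seed = seed)
    f2 <- file.path(out_dir, "apoptotic_index.csv")
    utils::write.csv(idx, f2, row.names = FALSE)
    add(f, f2, sidecar(f))
  } else {
    stop("unknown scenario: '", scenario, "'")
  }
  invisible(written)
}

#' Import an XPPAUT-style model file
#'
#' Parses the subset of the XPPAUT `.ode` dialect needed to exchange this
#' model: `par`/`param` lines (comma-separated `name=value` pairs),
#' first-order ODE definitions (`dX/dt=expr` or `X'=expr`), `init` lines,
#' and comments (`#`).  Parameter names matching [er_params()] fields
#' (case-insensitively; a trailing prime may be written `p`, e.g.
#' `kaau_p`) override the canonical defaults.  Other constructs are
#' collected in the parse report and warned about, not fatal; an empty
#' file is an error.
#'
#' @param path path to the `.ode` file.
#' @param base baseline parameters the overrides are applied to.
#' @return list with `params` (an `er_params`), `equations` (named
#'   character of right-hand-side expressions, as written), `init`
#'   (named numeric), and `unmatched` (character vector of lines or
#'   parameter names that could not be interpreted).
#' @export
import_ode_file <- function(path, base = er_params()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty .ode file: ", path)

  pars <- list(); eqs <- character(); init <- numeric(); unmatched <- character()
  for (ln in lines) {
    low <- tolower(ln)
    if (grepl("^(par|param|p)\\s", low)) {
      body <- sub("^\\S+\\s+", "", ln)
      for (kv in strsplit(body, ",")[[1]]) {
        kv <- strsplit(trimws(kv), "=")[[1]]
        if (length(kv) == 2 && !is.na(suppressWarnings(as.numeric(kv[2])))) {
          pars[[trimws(kv[1])]] <- as.numeric(kv[2])
        } else unmatched <- c(unmatched, paste(kv, collapse = "="))
      }
    } else if (grepl("^init\\s", low)) {
      body <- sub("^\\S+\\s+", "", ln)
      for (kv in strsplit(body, ",")[[1]]) {
        kv <- strsplit(trimws(kv), "=")[[1]]
        if (length(kv) == 2) init[trimws(kv[1])] <- as.numeric(kv[2])
      }
    } else if (grepl("^d[a-z0-9_]+/dt\\s*=", low)) {
      var <- sub("^d([A-Za-z0-9_]+)/dt.*$", "\\1", ln)
      eqs[var] <- sub("^[^=]*=", "", ln)
    } else if (grepl("^[a-z0-9_]+'\\s*=", low)) {
      var <- sub("^([A-Za-z0-9_]+)'.*$", "\\1", ln)
      eqs[var] <- sub("^[^=]*=", "", ln)
    } else if (grepl("^(@|done|aux\\s)", low)) {
      # numerics directives / aux outputs are irrelevant here
    } else {
      unmatched <- c(unmatched, ln)
    }
  }

  known <- names(unclass(base))
  p <- unclass(base)
  for (nm in names(pars)) {
    if (tolower(nm) == "s") next   # stressor level: protocol input, not a rate
    hit <- known[tolower(known) == tolower(nm)]
    if (length(hit) == 1) {
      p[[hit]] <- if (hit %in% c("n_steps", "Omega")) as.integer(pars[[nm]]) else pars[[nm]]
    } else {
      unmatched <- c(unmatched, nm)
    }
  }
  validate_er_params(p)
  class(p) <- "er_params"
  if (length(unmatched)) {
    warning("unmatched constructs in ", path, ": ",
            paste(utils::head(unmatched, 5), collapse = "; "))
  }
  list(params = p, equations = eqs, init = init, unmatched = unmatched)
}

#' Export the canonical model as an XPPAUT-style file
#'
#' Writes the parameter set and the canonical equations in the `.ode`
#' dialect accepted by [import_ode_file()] (round-trip safe for the
#' parameters).
#'
#' @param params an [er_params()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_ode_file <- function(params, path) {
  stopifnot(inherits(params, "er_params"))
  p <- unclass(params)
  n <- p$n_steps
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# autophagy-apoptosis crosstalk model under ER stress", con)
  for (nm in names(p)) {
    writeLines(sprintf("par %s=%.15g", nm, as.numeric(p[[nm]])), con)
  }
  writeLines("par S=1", con)
  writeLines("dERSS/dt=ka_e*S*(ERSS_T-ERSS)-ki_e*ERSS", con)
  writeLines(paste0(
    "dAUT/dt=(kaau+kaau_p*ERSS)*(AUT_T-AUT)/(J_aa+AUT_T-AUT)",
    "-(kiau+kiau_p*APO_", n, ")*AUT/(J_ia+AUT)"), con)
  pool <- paste0("(APO_T-", paste0("APO_", seq_len(n), collapse = "-"), ")")
  kb <- paste0("(kiap/(1+k_fb*APO_", n, ")+kiap_p*AUT)")
  for (i in seq_len(n)) {
    prev <- if (i == 1) pool else paste0("APO_", i - 1)
    rhs <- paste0("kaap*ERSS*", prev, "-", kb, "*APO_", i)
    if (i < n) rhs <- paste0(rhs, "-kaap*ERSS*APO_", i, "+", kb, "*APO_", i + 1)
    writeLines(paste0("dAPO_", i, "/dt=", rhs), con)
  }
  writeLines("done", con)
  invisible(path)
}
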