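#' Model parameters for the autophagy-apoptosis crosstalk network
#'
#' Constructs and validates the full kinetic parameter set of the model.
#' The network has three tiers: an ER stress sensor (ERSS) activated by the
#' stressor level `S`, a pro-survival autophagy inducer (AUT) activated by
#' the sensor through a Michaelis-Menten (zero-order-ultrasensitive)
#' activation/inactivation pair, and a pro-death apoptosis inducer (APO)
#' activated by the sensor through a chain of `n_steps` sequential
#' modification steps.  The two inducers antagonise each other: active APO
#' accelerates AUT inactivation (`kiau_p`) and active AUT accelerates the
#' per-step APO demodification (`kiap_p`).  Active APO additionally
#' suppresses its own demodification through a positive feedback of
#' strength `k_fb`, which makes the death decision effectively
#' irreversible once the chain is fully modified.
#'
#' Default values are the package's calibrated reference set: they were
#' fixed once by [calibrate()] against the model's behavioural anchors
#' (apoptosis threshold between stress levels 3 and 5 at 240 min,
#' commitment window 30-90 min under washout of `S0 = 10`, about 95%
#' apoptotic ensembles at the latest washout time) and are shipped in
#' `inst/extdata/default_params.yaml`.
#'
#' @param ERSS_T,AUT_T,APO_T total amounts of sensor, autophagy inducer and
#'   apoptosis inducer (dimensionless concentration units).
#' @param ka_e,ki_e sensor activation (per stress unit per min) and
#'   inactivation (1/min) rate constants.
#' @param kaau basal autophagy activation rate (1/min).
#' @param kaau_p sensor-dependent autophagy activation rate constant
#'   (1/(conc min)); the modulation handle for autophagy inhibitors
#'   (3-MA-like, lower values) and activators (metyrapone-like, higher
#'   values).
#' @param J_aa,J_ia Michaelis constants of autophagy activation and
#'   inactivation (concentration units).
#' @param kiau basal autophagy inactivation rate (1/min).
#' @param kiau_p apoptosis-inducer-dependent autophagy inactivation rate
#'   constant (1/(conc min)).
#' @param kaap sensor-dependent per-step apoptosis activation rate constant
#'   (1/(conc min)).
#' @param kiap basal per-step apoptosis deactivation rate (1/min).
#' @param kiap_p autophagy-dependent per-step apoptosis deactivation rate
#'   constant (1/(conc min)).
#' @param n_steps number of sequential activating modification steps of the
#'   apoptosis inducer (integer >= 2; the multistep chain is what gives the
#'   death switch its sigmoidal response).
#' @param k_fb strength of the positive feedback by which active APO
#'   suppresses its own deactivation (dimensionless, >= 0).
#' @param sigma_S standard deviation (log scale) of the per-cell mean-one
#'   lognormal variability of the stressor level in stochastic ensembles
#'   (extrinsic noise in perceived stress strength); 0 disables it.  The
#'   calibrated default is 0.26: intrinsic copy-number noise alone does not
#'   reproduce the observed cell-to-cell dispersion of commitment times.
#' @param Omega system size: molecule count per unit concentration in the
#'   stochastic engine.  `Omega * ERSS_T` etc. are rounded to integer copy
#'   numbers.
#'
#' @return An object of class `er_params`: a named list of validated
#'   parameters.
#' @export
#' @examples
#' p <- er_params()
#' p$kaap
#' p2 <- er_params(kaau_p = 0.2)  # autophagy-inhibited variant
er_params <- function(ERSS_T = 1, AUT_T = 1, APO_T = 1,
                      ka_e = 0.009, ki_e = 0.171,
                      kaau = 0.096, kaau_p = 0.45,
                      J_aa = 0.043, J_ia = 0.02,
                      kiau = 0.1, kiau_p = 1.5,
                      kaap = 0.414, kiap = 1.32, kiap_p = 0.177,
                      n_steps = 3L, k_fb = 3000,
                      sigma_S = 0.26, Omega = 100L) {
  p <- list(ERSS_T = ERSS_T, AUT_T = AUT_T, APO_T = APO_T,
            ka_e = ka_e, ki_e = ki_e,
            kaau = kaau, kaau_p = kaau_p, J_aa = J_aa, J_ia = J_ia,
            kiau = kiau, kiau_p = kiau_p,
            kaap = kaap, kiap = kiap, kiap_p = kiap_p,
            n_steps = as.integer(n_steps), k_fb = k_fb,
            sigma_S = sigma_S, Omega = as.integer(Omega))
  validate_er_params(p)
  class(p) <- "er_params"
  p
}

validate_er_params <- function(p) {
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) {
    stop("non-numeric parameter: ", paste(names(p)[!num], collapse = ", "))
  }
  for (nm in c("ERSS_T", "AUT_T", "APO_T")) {
    if (p[[nm]] <= 0) stop("total amount '", nm, "' must be > 0")
  }
  rates <- c("ka_e", "ki_e", "kaau", "kaau_p", "J_aa", "J_ia", "kiau",
             "kiau_p", "kaap", "kiap", "kiap_p", "k_fb", "sigma_S")
  for (nm in rates) {
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be >= 0")
  }
  if (p$n_steps < 1L) stop("n_steps must be a positive integer")
  if (p$n_steps < 2L) {
    warning("n_steps = 1 is below the multistep regime: switch-like ",
            "apoptosis activation is not guaranteed (reference behaviour ",
            "requires n_steps >= 2)")
  }
  if (p$Omega < 1L) stop("Omega must be a positive integer")
  invisible(p)
}

#' @export
print.er_params <- function(x, ...) {
  cat("<er_params> autophagy-apoptosis crosstalk parameter set\n")
  cat(sprintf("  totals: ERSS_T=%g AUT_T=%g APO_T=%g  (Omega=%d, n_steps=%d)\n",
              x$ERSS_T, x$AUT_T, x$APO_T, x$Omega, x$n_steps))
  cat(sprintf("  sensor: ka_e=%g ki_e=%g\n", x$ka_e, x$ki_e))
  cat(sprintf("  autophagy: kaau=%g kaau_p=%g J_aa=%g J_ia=%g kiau=%g kiau_p=%g\n",
              x$kaau, x$kaau_p, x$J_aa, x$J_ia, x$kiau, x$kiau_p))
  cat(sprintf("  apoptosis: kaap=%g kiap=%g kiap_p=%g k_fb=%g\n",
              x$kaap, x$kiap, x$kiap_p, x$k_fb))
  if (x$sigma_S > 0) cat(sprintf("  extrinsic stress noise: sigma_S=%g\n", x$sigma_S))
  invisible(x)
}

#' Copy a parameter set with a modified autophagy activation strength
#'
#' Models pharmacological modulation of autophagy: pretreatment with an
#' autophagy inhibitor (3-MA-like) corresponds to lowering the
#' sensor-dependent autophagy activation constant (e.g. `kaau_p = 0.2`),
#' an activator (metyrapone-like) to raising it (e.g. `kaau_p = 0.7`).
#' The change applies for the whole simulated run.
#'
#' @param params an [er_params()] object.
#' @param kaau_p_new new value of `kaau_p` (>= 0).
#' @return a new `er_params` object; the input is not modified.
#' @export
modulate_autophagy <- function(params, kaau_p_new) {
  stopifnot(inherits(params, "er_params"))
  if (!is.numeric(kaau_p_new) || length(kaau_p_new) != 1L || kaau_p_new < 0) {
    stop("kaau_p_new must be a single number >= 0")
  }
  p <- unclass(params)
  p$kaau_p <- kaau_p_new
  validate_er_params(p)
  class(p) <- "er_params"
  p
}

#' Read / write parameter sets as flat YAML key-value files
#'
#' The config dialect is a flat YAML mapping whose keys are exactly the
#' [er_params()] field names; unknown keys are an error so that typos in
#' configs fail loudly.  Missing keys fall back to the calibrated defaults.
#'
#' @param path file path.
#' @param params an `er_params` object (for writing).
#' @return `read_params()` returns an `er_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) stop("empty parameter file: ", path)
  known <- names(formals(er_params))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  do.call(er_params, raw)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "er_params"))
  yaml::write_yaml(lapply(unclass(params), function(x) {
    if (is.integer(x)) x else as.numeric(x)
  }), path, precision = 15L)
  invisible(path)
}

#' The calibrated default parameter file shipped with the package
#'
#' @return path to `default_params.yaml` under the installed package.
#' @export
default_params_file <- function() {
  system.file("extdata", "default_params.yaml", package = "erfate",
              mustWork = TRUE)
}

# Stable short hash of a parameter set, echoed into result sidecars so any
# output table is traceable to the exact kinetics that produced it.
params_hash <- function(params) {
  v <- unlist(unclass(params))
  txt <- paste(names(v), format(v, digits = 15), sep = "=", collapse = ";")
  # simple polynomial rolling hash over codepoints (no digest dependency)
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
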