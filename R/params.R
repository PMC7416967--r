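# Parameter set -------------------------------------------------------------

# Canonical ordering of the parameter vector handed to the compiled
# derivative function.  src/vsm_deriv.c indexes this vector by position, so
# the order here and the #defines there must stay in lockstep (guarded by a
# test comparing the R and C right-hand sides).
.param_order <- c(
  "K_CaM", "CaM_tot", "K_B", "B_tot",
  "Myo_tot", "gamma_cross", "K2", "K3", "K4", "K5", "K7", "ca_per_myosin",
  "eta_IP3", "kdeg_IP3", "k_c", "PIP2_rr", "PIP2_tot", "G_conc",
  "nu_mcu", "nu_nclx", "K_mcu1", "K_mcu2", "L_mcu", "p1", "p2", "dPsi_m",
  "nu_mit_leak",
  "K_CalC", "CalC_tot", "K_CalP", "CalP_tot",
  "K1_serca", "K3_serca", "k2_serca", "km2_serca", "k4_serca", "km4_serca",
  "SERCA_tot", "serca_scale",
  "nu_ipr", "a1", "a2", "a3", "a4", "a5", "b1", "b2", "b3", "b4", "b5",
  "nu_ryr", "Kr1", "Kr2", "Kmr1", "Kmr2",
  "phi_ecs", "Na_cyt", "Na_ecs", "eta_ncx", "d_ncx", "k_ncx1", "Q_ncx",
  "Q_pmca", "k_pmca", "Q_vocc", "g_leak_ecs", "Faraday",
  "r_ercyt", "r_mitcyt", "V_cyt",
  "Ca_ecs", "Ca_mit", "RT_over_2F",
  "alpha_er", "alpha_mit", "alpha_pm",
  "ca_floor", "protons_per_Ca", "protons_per_ATP")

.state_names <- c("ca_cyt", "ca_er", "ip3", "pip2", "Mp", "AMp", "AM",
                  "X00", "X01", "X10", "R10", "R11", "R01",
                  "ca_sink", "ca_source")

#' Model parameters for the vascular smooth muscle calcium model
#'
#' Builds the full parameter set of the whole-cell calcium model. Defaults
#' reproduce the published reference parameterization: cytosolic buffers and
#' the cross-bridge and IP3/PIP2 constants, mitochondrial MCU/NCLX/leak
#' constants, ER buffers, SERCA, IP3R and RyR gating constants, and the
#' plasma-membrane NCX/VOCC/PMCA/leak constants. Three of the constants
#' (`nu_mit_leak`, `Q_ncx`, `serca_scale`) are calibration targets: their
#' defaults are `NA` and they are filled in by [vsm_model()] so that the
#' resting state (0.1 uM cytosolic, 500 uM ER, 1300 uM extracellular free
#' calcium) is an exact fixed point.
#'
#' All concentrations are in uM (including sodium), rates in 1/s or uM/s,
#' potentials in mV, volumes in pL. `RT_over_2F` is derived from
#' `temperature_K` and `Faraday`.
#'
#' @param ... named overrides of any parameter, e.g. `Ca_mit = 0.25` or
#'   `alpha_er = 0.5`. Unknown names are an error.
#' @param temperature_K temperature used for the Nernst potentials (K).
#' @return An object of class `vsm_params`: a named list of numeric scalars.
#' @examples
#' p <- vsm_params(Ca_mit = 0.25)
#' p$Ca_mit
#' @export
vsm_params <- function(..., temperature_K = 310) {
  p <- list(
    # cytosolic buffers (calmodulin + lumped "other"), rapid-buffer approx.
    K_CaM = 0.26, CaM_tot = 30, K_B = 0.53, B_tot = 30,
    # four-state cross-bridge (latch) model; K1 = K6 = gamma_cross * c^3
    Myo_tot = 10, gamma_cross = 17,
    K2 = 0.5, K3 = 0.4, K4 = 0.1, K5 = 0.5, K7 = 0.1,
    ca_per_myosin = 1,
    # IP3 / PIP2 turnover; G-protein concentration fixed
    eta_IP3 = 11.725, kdeg_IP3 = 1.25, k_c = 0.4,
    PIP2_rr = 0.1, PIP2_tot = 118.61, G_conc = 3.314e-5,
    # mitochondria: uniporter, Na/Ca exchanger, Ohmic leak (calibrated)
    nu_mcu = 4.4e-6, nu_nclx = 0.13, K_mcu1 = 6, K_mcu2 = 0.38, L_mcu = 50,
    p1 = 0.1, p2 = 0.0161, dPsi_m = 140, nu_mit_leak = NA_real_,
    # ER luminal buffers (sites C and P of calreticulin-like buffering)
    K_CalC = 2000, CalC_tot = 7200, K_CalP = 10, CalP_tot = 720,
    # SERCA two-state cycle; rate constants carry the pump-speed factor 10
    K1_serca = 0.7, K3_serca = 1.111111e-5,
    k2_serca = 6, km2_serca = 9.7, k4_serca = 4, km4_serca = 0.012,
    SERCA_tot = 182, serca_scale = NA_real_,
    # IP3R: De Young-Keizer binding constants, four-state reduction
    nu_ipr = 1000,
    a1 = 167.6, a2 = 3.81, a3 = 413.4, a4 = 0.3101, a5 = 53.9,
    b1 = 228, b2 = 0.409, b3 = 188.5, b4 = 0.096, b5 = 4.52,
    # RyR four-state gating
    nu_ryr = 0.2, Kr1 = 2.5, Kr2 = 1.5, Kmr1 = 7.6, Kmr2 = 84,
    # plasma membrane: NCX (calibrated prefactor), VOCC, PMCA, leak
    phi_ecs = -54, Na_cyt = 8000, Na_ecs = 140000, eta_ncx = 0.35,
    d_ncx = 1e8, k_ncx1 = 0.125, Q_ncx = NA_real_,
    Q_pmca = 0.04, k_pmca = 0.15, Q_vocc = 0.10, g_leak_ecs = 3e-5,
    Faraday = 96487,
    # geometry: cytosol/ER and cytosol/mitochondria volume ratios
    r_ercyt = 10, r_mitcyt = 13.6, V_cyt = 0.7,
    # environment: bulk ECS bath; matrix held at saturation concentration
    Ca_ecs = 1300, Ca_mit = 0.1,
    temperature_K = temperature_K,
    RT_over_2F = NA_real_,
    # compartment flux rescalings (identity = reference model)
    alpha_er = 1, alpha_mit = 1, alpha_pm = 1,
    # numerical floor guarding the NCLX / Nernst singularities at c -> 0
    ca_floor = 1e-6,
    # ATP bookkeeping: protons bound per dissolved calcium, protons per ATP
    protons_per_Ca = 2, protons_per_ATP = 3)

  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(dots)] <- lapply(dots, as.numeric)
  }
  # RT/2F in mV; override wins if explicitly supplied
  if (is.na(p$RT_over_2F))
    p$RT_over_2F <- 1000 * 8.31446261815324 * p$temperature_K / (2 * p$Faraday)
  class(p) <- "vsm_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  must_pos <- setdiff(.param_order,
                      c("phi_ecs", "nu_mit_leak", "Q_ncx", "serca_scale",
                        "alpha_er", "alpha_mit", "alpha_pm"))
  for (nm in must_pos) {
    v <- p[[nm]]
    if (!is.na(v) && v <= 0 && nm != "phi_ecs")
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  }
  for (nm in c("alpha_er", "alpha_mit", "alpha_pm"))
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("'", nm, "' must be finite and >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.vsm_params <- function(x, ...) {
  calib <- c("nu_mit_leak", "Q_ncx", "serca_scale")
  done <- !vapply(x[calib], is.na, logical(1))
  cat("<vsm_params> ", length(.param_order), " constants; Ca_mit = ",
      format(x$Ca_mit), " uM; alpha = (",
      paste(format(unlist(x[c("alpha_er", "alpha_mit", "alpha_pm")])),
            collapse = ", "), ")\n", sep = "")
  cat("  calibrated constants ",
      if (all(done)) "set" else "unset (run vsm_model())", "\n", sep = "")
  invisible(x)
}

# parameter vector in the canonical order expected by the compiled RHS
as_parms_vector <- function(p) {
  stopifnot(inherits(p, "vsm_params"))
  v <- vapply(.param_order, function(nm) as.numeric(p[[nm]]), numeric(1))
  if (anyNA(v))
    stop("parameter set contains uncalibrated constants; run vsm_model()",
         call. = FALSE)
  v
}
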