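# Membrane fluxes -----------------------------------------------------------
# Sign convention: every flux is cytosol-volume-referenced (uM/s) and
# positive when it raises free cytosolic calcium.

#' Mitochondrial calcium uniporter (MCU) flux
#'
#' Unidirectional uptake from cytosol to matrix with allosteric calcium
#' activation and voltage factor `exp(p1 * dPsi_m)`; always <= 0.
#'
#' @param ca_cyt free cytosolic calcium (uM), >= 0; vectorized.
#' @param params a [vsm_params()] object.
#' @return flux (uM/s), <= 0.
#' @export
flux_mcu <- function(ca_cyt, params) {
  x <- ca_cyt / params$K_mcu1
  -params$nu_mcu * x * (1 + x)^3 /
    ((1 + x)^4 + params$L_mcu * (1 + ca_cyt / params$K_mcu2)^2.3) *
    exp(params$p1 * params$dPsi_m)
}

#' Mitochondrial Na/Ca exchanger (NCLX) flux
#'
#' Matrix-to-cytosol extrusion `nu_nclx * (Ca_mit/Ca_cyt) * exp(p2 dPsi_m)`.
#' Singular at `ca_cyt = 0`; the integrator applies the `ca_floor` guard,
#' scalar evaluation refuses zero.
#'
#' @param ca_mit matrix free calcium (uM).
#' @inheritParams flux_mcu
#' @return flux (uM/s), >= 0.
#' @export
flux_nclx <- function(ca_cyt, ca_mit, params) {
  if (any(ca_cyt <= 0)) stop("ca_cyt must be > 0 for NCLX", call. = FALSE)
  params$nu_nclx * (ca_mit / ca_cyt) * exp(params$p2 * params$dPsi_m)
}

#' Nernst potential across the inner mitochondrial membrane
#' @inheritParams flux_nclx
#' @return potential (mV): `RT/2F * log(ca_mit / ca_cyt)`.
#' @export
nernst_mit <- function(ca_mit, ca_cyt, params) {
  if (any(ca_mit <= 0) || any(ca_cyt <= 0))
    stop("concentrations must be > 0 for a Nernst potential", call. = FALSE)
  params$RT_over_2F * log(ca_mit / ca_cyt)
}

#' Ohmic mitochondrial leak flux
#'
#' Non-specific conductance driven by the difference between the calcium
#' Nernst potential and the (fixed) membrane potential. The conductance
#' `nu_mit_leak` is calibrated so total mitochondrial flux vanishes at the
#' resting state.
#'
#' @inheritParams flux_nclx
#' @return flux (uM/s).
#' @export
flux_mit_leak <- function(ca_mit, ca_cyt, params) {
  params$nu_mit_leak * (nernst_mit(ca_mit, ca_cyt, params) - params$dPsi_m)
}

#' SERCA pump flux
#'
#' Two-state reduced SERCA cycle (calcium-binding steps at fast
#' equilibrium) with normalized concentrations `c/K1_serca` and
#' `ca_er * K3_serca`. Negative when pumping cytosol to ER, which is the
#' case whenever `ca_cyt/ca_er` exceeds the thermodynamic equilibrium ratio
#' `K1_serca * K3_serca * sqrt(km2 km4 / (k2 k4))`. The calibrated
#' `serca_scale` sets the pump density so the ER is balanced at rest.
#'
#' @param ca_er free ER calcium (uM).
#' @inheritParams flux_mcu
#' @return flux (uM/s).
#' @export
flux_serca <- function(ca_cyt, ca_er, params) {
  chat2 <- (ca_cyt / params$K1_serca)^2
  shat2 <- (ca_er * params$K3_serca)^2
  k2 <- params$k2_serca; km2 <- params$km2_serca
  k4 <- params$k4_serca; km4 <- params$km4_serca
  num <- 2 * (km2 * km4 * shat2 - k2 * k4 * chat2) * params$SERCA_tot
  den <- chat2 * shat2 * (k2 + km2) + chat2 * (k2 + k4) +
    shat2 * (km2 + km4) + (k4 + km4)
  params$serca_scale * num / den
}

#' IP3 receptor flux
#'
#' Channel open probability `X10^4 + 4 X10^3 (1 - X10)` (at least three of
#' four subunits activated and non-inactivated) times the ER-cytosol
#' gradient.
#'
#' @param X10 probability of the conducting subunit state.
#' @inheritParams flux_serca
#' @return flux (uM/s), positive for ER-to-cytosol release.
#' @export
flux_ipr <- function(X10, ca_cyt, ca_er, params) {
  params$nu_ipr * (X10^4 + 4 * X10^3 * (1 - X10)) * (ca_er - ca_cyt)
}

#' Ryanodine receptor flux
#' @param R10 probability of the open (activation-bound) RyR state.
#' @inheritParams flux_serca
#' @return flux (uM/s), positive for ER-to-cytosol release.
#' @export
flux_ryr <- function(R10, ca_cyt, ca_er, params) {
  params$nu_ryr * R10^2 * (ca_er - ca_cyt)
}

#' Plasma membrane Na/Ca exchanger (NCX) flux
#'
#' Electrodiffusive exchanger with fixed sodium concentrations, forward and
#' reverse voltage factors at the energy-barrier position `eta_ncx`, and
#' allosteric calcium activation `1/(1 + (k_ncx1/c)^2)`. The dimensional
#' prefactor is the calibrated constant `Q_ncx`; all concentrations enter
#' in uM.
#'
#' @inheritParams flux_mcu
#' @return flux (uM/s), negative (extrusion) at and above resting calcium.
#' @export
flux_ncx <- function(ca_cyt, params) {
  v <- params$phi_ecs / (2 * params$RT_over_2F)     # phi * F / RT
  phiF <- exp(params$eta_ncx * v)
  phiR <- exp((params$eta_ncx - 1) * v)
  drive <- (params$Na_cyt^3 * params$Ca_ecs * phiF -
              params$Na_ecs^3 * ca_cyt * phiR) /
    (1 + params$d_ncx * (ca_cyt * params$Na_ecs^3 +
                           params$Ca_ecs * params$Na_cyt^3))
  act <- ifelse(ca_cyt > 0, 1 / (1 + (params$k_ncx1 / ca_cyt)^2), 0)
  params$Q_ncx * drive * act
}

#' Nernst potential across the plasma membrane
#' @inheritParams flux_mcu
#' @return potential (mV).
#' @export
nernst_ecs <- function(ca_cyt, params) {
  if (any(ca_cyt <= 0))
    stop("ca_cyt must be > 0 for a Nernst potential", call. = FALSE)
  params$RT_over_2F * log(params$Ca_ecs / ca_cyt)
}

#' Voltage-operated calcium channel (VOCC) flux
#'
#' `Q_vocc * dbar * fbar * (E_Ca_ecs - phi_ecs)` with logistic activation
#' (`dbar`) and inactivation (`fbar`) gates evaluated at the fixed membrane
#' potential.
#'
#' @inheritParams flux_mcu
#' @return flux (uM/s), positive influx at rest.
#' @export
flux_vocc <- function(ca_cyt, params) {
  dbar <- 1 / (1 + exp(-params$phi_ecs / 8.3))
  fbar <- 1 / (1 + exp((params$phi_ecs + 42) / 9.1))
  params$Q_vocc * dbar * fbar * (nernst_ecs(ca_cyt, params) - params$phi_ecs)
}

#' Plasma membrane leak and PMCA fluxes
#'
#' Non-specific Ohmic leak `-g_leak_ecs * (phi_ecs - E_Ca_ecs)` and the
#' saturable PMCA pump `-Q_pmca * c / (c + k_pmca)`.
#'
#' @inheritParams flux_mcu
#' @return named numeric length 2: `J_ecs_leak`, `J_pmca` (uM/s).
#' @export
flux_pm_leak_pmca <- function(ca_cyt, params) {
  c(J_ecs_leak = -params$g_leak_ecs *
      (params$phi_ecs - nernst_ecs(ca_cyt, params)),
    J_pmca = -params$Q_pmca * ca_cyt / (ca_cyt + params$k_pmca))
}

#' ATP production rate equivalent of the mitochondrial calcium flux
#'
#' Calcium-phosphate dissolution consumes matrix protons
#' (`protons_per_Ca` per calcium) and three protons removed equate to one
#' ATP, so the ATP-equivalent rate is
#' `protons_per_Ca * J_mit_to_cyt / protons_per_ATP`. Positive when the
#' matrix is emptying (proton gradient reinforced).
#'
#' @param J_mit_to_cyt net mitochondria-to-cytosol flux (uM/s).
#' @inheritParams flux_mcu
#' @return ATP production rate (uM/s, cytosol-volume-referenced).
#' @export
atp_rate <- function(J_mit_to_cyt, params) {
  params$protons_per_Ca * J_mit_to_cyt / params$protons_per_ATP
}

#' Flux decomposition at a model state
#'
#' Evaluates every membrane flux and the three compartment aggregates at one
#' or more states. Aggregates include the compartment rescaling factors
#' `alpha_er`, `alpha_mit`, `alpha_pm` exactly as they enter the equations
#' of motion.
#'
#' @param state named numeric vector (one state) or data.frame/matrix with
#'   the model state columns.
#' @param params a calibrated [vsm_params()] object.
#' @return data.frame of per-mechanism fluxes and aggregates (uM/s).
#' @export
flux_breakdown <- function(state, params) {
  s <- if (is.null(dim(state))) as.data.frame(as.list(state)) else
    as.data.frame(state)
  c_eff <- pmax(s$ca_cyt, params$ca_floor)
  dmyoMp_AMp <- mapply(function(Mp, AMp, AM, cc) {
    d <- myosin_rhs(Mp, AMp, AM, cc, params); d[[1]] + d[[2]]
  }, s$Mp, s$AMp, s$AM, c_eff)
  out <- data.frame(
    J_mcu = flux_mcu(c_eff, params),
    J_nclx = flux_nclx(c_eff, params$Ca_mit, params),
    J_mit_leak = flux_mit_leak(params$Ca_mit, c_eff, params),
    J_serca = flux_serca(c_eff, s$ca_er, params),
    J_ipr = flux_ipr(s$X10, c_eff, s$ca_er, params),
    J_ryr = flux_ryr(s$R10, c_eff, s$ca_er, params),
    J_ncx = flux_ncx(c_eff, params),
    J_vocc = flux_vocc(c_eff, params),
    J_pmca = -params$Q_pmca * c_eff / (c_eff + params$k_pmca),
    J_ecs_leak = -params$g_leak_ecs *
      (params$phi_ecs - nernst_ecs(c_eff, params)),
    J_cyt_cyt = -params$ca_per_myosin * params$Myo_tot * dmyoMp_AMp)
  out$J_mit_to_cyt <- params$alpha_mit *
    (out$J_mcu + out$J_nclx + out$J_mit_leak)
  out$J_er_to_cyt <- params$alpha_er * (out$J_serca + out$J_ipr + out$J_ryr)
  out$J_ecs_to_cyt <- params$alpha_pm *
    (out$J_ecs_leak + out$J_pmca + out$J_ncx + out$J_vocc)
  out
}
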