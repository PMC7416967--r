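# Gating subsystems: cross-bridges, IP3/PIP2, IP3R, RyR ---------------------

#' Cross-bridge (latch) kinetics
#'
#' Four-state actin/myosin model: free (M), phosphorylated (Mp), attached
#' phosphorylated (AMp) and attached dephosphorylated latch (AM) cross
#' bridges, with M eliminated by conservation `M = 1 - Mp - AMp - AM`.
#' Phosphorylation rates K1 = K6 = `gamma_cross * ca_cyt^3` carry the
#' calcium dependence.
#'
#' @param Mp,AMp,AM state fractions in \[0, 1\].
#' @param ca_cyt free cytosolic calcium (uM).
#' @param params a [vsm_params()] object.
#' @return numeric length 3: d(Mp, AMp, AM)/dt (1/s).
#' @export
myosin_rhs <- function(Mp, AMp, AM, ca_cyt, params) {
  K1 <- params$gamma_cross * ca_cyt^3
  M <- 1 - Mp - AMp - AM
  c(dMp  = params$K4 * AMp + K1 * M - (params$K2 + params$K3) * Mp,
    dAMp = params$K3 * Mp + K1 * AM - (params$K4 + params$K5) * AMp,
    dAM  = params$K5 * AMp - (params$K7 + K1) * AM)
}

#' Tension fraction generated by attached cross bridges
#'
#' Contractile tension is proportional to the attached fraction; the
#' proportionality constant is taken as 1 so tension is reported as the
#' fraction `AMp + AM`.
#'
#' @param state named vector or list with `AMp` and `AM` entries.
#' @return dimensionless tension fraction in \[0, 1\].
#' @export
tension_fraction <- function(state) {
  as.numeric(state[["AMp"]]) + as.numeric(state[["AM"]])
}

#' Calcium flux bound/released by myosin phosphorylation
#'
#' Phosphorylated heads sequester calcium, so net phosphorylation draws
#' free calcium out of the cytosol:
#' `J = -ca_per_myosin * Myo_tot * d(Mp + AMp)/dt`.
#'
#' @param dmyo derivatives from [myosin_rhs()].
#' @inheritParams myosin_rhs
#' @return flux (uM/s), positive raises cytosolic calcium.
#' @export
myosin_ca_flux <- function(dmyo, params) {
  -params$ca_per_myosin * params$Myo_tot * (dmyo[[1]] + dmyo[[2]])
}

#' IP3 and PIP2 turnover
#'
#' PLC-delta production of IP3 from PIP2 at calcium-dependent rate
#' `r_h = eta_IP3 * c/(k_c + c) * G_conc`, first-order IP3 degradation, and
#' PIP2 replenishment from a conserved lipid pool.
#'
#' @param ip3,pip2 concentrations (uM).
#' @inheritParams myosin_rhs
#' @return numeric length 2: d(IP3, PIP2)/dt (uM/s).
#' @export
ip3_pip2_rhs <- function(ip3, pip2, ca_cyt, params) {
  rh <- params$eta_IP3 * ca_cyt / (params$k_c + ca_cyt) * params$G_conc
  c(dip3  = rh * pip2 - params$kdeg_IP3 * ip3,
    dpip2 = -(rh + params$PIP2_rr) * pip2 +
      params$PIP2_rr * (params$PIP2_tot - ip3))
}

# Effective IP3R transition rates of the four-state De Young-Keizer
# reduction with the IP3-binding site at fast equilibrium.  States are
# X(activation, inactivation); k_i = b_i / (a_i * IP3) for i = 1 (no Ca on
# the inactivation site) and i = 3 (Ca on the inactivation site), so
# 1/(1+k1), 1/(1+k3) are the IP3-bound fractions of those state pairs.
ip3r_rates <- function(ca_cyt, ip3, params) {
  if (any(ip3 <= 0)) stop("ip3 must be > 0 for IP3R gating", call. = FALSE)
  k1 <- params$b1 / (params$a1 * ip3)
  k3 <- params$b3 / (params$a3 * ip3)
  list(
    act0   = params$a5 * ca_cyt / (1 + k1),                 # X00 -> X10
    act1   = params$a5 * ca_cyt / (1 + k3),                 # X01 -> X11
    deact  = params$b5,                                     # X10->X00, X11->X01
    inact0 = (params$a2 + params$a4 * k1) * ca_cyt / (1 + k1), # X00 -> X01
    rec0   = (params$b2 + params$b4 * k3) / (1 + k3),       # X01 -> X00
    inact1 = params$a2 * ca_cyt,                            # X10 -> X11
    rec1   = params$b2)                                     # X11 -> X10
}

#' IP3 receptor gating kinetics
#'
#' Four-state reduction of the De Young-Keizer IP3R model with the IP3
#' binding site in fast equilibrium. States X_ij are indexed by (calcium on
#' the activation site, calcium on the inactivation site); X11 is eliminated
#' by conservation `X11 = 1 - X00 - X01 - X10`. The channel conducts when
#' at least three of four subunits are in the activated, non-inactivated
#' state X10 (see [flux_ipr()]).
#'
#' @param X00,X01,X10 retained state probabilities.
#' @param ip3 IP3 concentration (uM), > 0.
#' @inheritParams myosin_rhs
#' @return numeric length 3: d(X00, X01, X10)/dt (1/s).
#' @export
ip3r_rhs <- function(X00, X01, X10, ca_cyt, ip3, params) {
  r <- ip3r_rates(ca_cyt, ip3, params)
  X11 <- 1 - X00 - X01 - X10
  c(dX00 = -(r$act0 + r$inact0) * X00 + r$rec0 * X01 + r$deact * X10,
    dX01 = r$inact0 * X00 - (r$rec0 + r$act1) * X01 + r$deact * X11,
    dX10 = r$act0 * X00 - (r$deact + r$inact1) * X10 + r$rec1 * X11)
}

#' Ryanodine receptor gating kinetics
#'
#' Four-state RyR model: R00 free, R10 calcium on the activation sites
#' (cooperative, rate `Kr1 c^2`), R01 calcium on the inactivation site
#' (rate `Kr2 c`), R11 both. R00 is eliminated by conservation. The open
#' state is R10 (see [flux_ryr()]).
#'
#' @param R10,R11,R01 retained state probabilities.
#' @inheritParams myosin_rhs
#' @return numeric length 3: d(R10, R11, R01)/dt (1/s).
#' @export
ryr_rhs <- function(R10, R11, R01, ca_cyt, params) {
  R00 <- 1 - R10 - R11 - R01
  ka <- params$Kr1 * ca_cyt^2
  ki <- params$Kr2 * ca_cyt
  c(dR10 = ka * R00 - (params$Kmr1 + ki) * R10 + params$Kmr2 * R11,
    dR11 = ki * R10 + ka * R01 - (params$Kmr2 + params$Kmr1) * R11,
    dR01 = ki * R00 - (params$Kmr2 + ka) * R01 + params$Kmr1 * R11)
}

# solve the fixed point of an affine 3-state system given its rhs closure
solve_affine3 <- function(f) {
  b <- f(0, 0, 0)
  A <- cbind(f(1, 0, 0) - b, f(0, 1, 0) - b, f(0, 0, 1) - b)
  as.numeric(solve(A, -b))
}

#' Steady state of the IP3/PIP2 subsystem
#'
#' Closed-form fixed point of the two-variable IP3/PIP2 system at a fixed
#' cytosolic calcium.
#'
#' @inheritParams myosin_rhs
#' @return named numeric: `ip3`, `pip2` (uM).
#' @export
ip3_steady <- function(ca_cyt, params) {
  rh <- params$eta_IP3 * ca_cyt / (params$k_c + ca_cyt) * params$G_conc
  if (rh == 0) return(c(ip3 = 0, pip2 = params$PIP2_tot))
  ip3 <- rh * params$PIP2_rr * params$PIP2_tot /
    (params$kdeg_IP3 * (rh + params$PIP2_rr) + rh * params$PIP2_rr)
  c(ip3 = ip3, pip2 = params$kdeg_IP3 * ip3 / rh)
}

#' Steady states of the IP3R and RyR gates
#'
#' Linear solves of the two affine 3x3 gating systems plus conservation.
#'
#' @param ip3 IP3 concentration (uM); defaults to its own fixed point at
#'   `ca_cyt`.
#' @inheritParams myosin_rhs
#' @return named numeric with X00, X01, X10, X11, R00, R10, R11, R01.
#' @export
gate_steady <- function(ca_cyt, params, ip3 = NULL) {
  if (is.null(ip3)) ip3 <- ip3_steady(ca_cyt, params)[["ip3"]]
  X <- solve_affine3(function(a, b, c.)
    ip3r_rhs(a, b, c., ca_cyt, ip3, params))
  R <- solve_affine3(function(a, b, c.)
    ryr_rhs(a, b, c., ca_cyt, params))
  c(X00 = X[1], X01 = X[2], X10 = X[3], X11 = 1 - sum(X),
    R00 = 1 - sum(R), R10 = R[1], R11 = R[2], R01 = R[3])
}

#' Steady state of the cross-bridge subsystem
#' @inheritParams myosin_rhs
#' @return named numeric: M, Mp, AMp, AM.
#' @export
myosin_steady <- function(ca_cyt, params) {
  m <- solve_affine3(function(a, b, c.)
    myosin_rhs(a, b, c., ca_cyt, params))
  c(M = 1 - sum(m), Mp = m[1], AMp = m[2], AM = m[3])
}
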