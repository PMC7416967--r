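# Full right-hand side ------------------------------------------------------

#' Right-hand side of the whole-cell calcium model
#'
#' Mass balance for the 15 model states: free cytosolic and ER calcium
#' (rapid-buffer divisors), IP3/PIP2, three cross-bridge fractions, three
#' IP3R and three RyR gate probabilities, and the two clearance
#' accumulators (`ca_sink`: cumulative efflux to the extracellular space;
#' `ca_source`: cumulative mitochondrial release). Matrix calcium is held
#' constant (quasi-steady dissolution/aggregation of calcium-phosphate
#' clusters). Compartment aggregates are rescaled by the `alpha_*`
#' factors before entering the balance.
#'
#' This is the plain-R reference implementation, in the argument form used
#' by [deSolve::ode()]; [simulate.vsm_model()] integrates an equivalent
#' compiled version for speed.
#'
#' @param t time (s, unused; the system is autonomous).
#' @param y named state vector (see `mitovasc:::.state_names`).
#' @param params a calibrated [vsm_params()] object.
#' @return `list(dy)` as expected by deSolve.
#' @export
vsm_rhs <- function(t, y, params) {
  p <- params
  cc <- max(y[[1]], p$ca_floor)
  ca_er <- y[[2]]; ip3 <- y[[3]]; pip2 <- y[[4]]
  Mp <- y[[5]]; AMp <- y[[6]]; AM <- y[[7]]
  X00 <- y[[8]]; X01 <- y[[9]]; X10 <- y[[10]]
  R10 <- y[[11]]; R11 <- y[[12]]; R01 <- y[[13]]

  J_er <- p$alpha_er * (flux_serca(cc, ca_er, p) +
                          flux_ipr(X10, cc, ca_er, p) +
                          flux_ryr(R10, cc, ca_er, p))
  J_mit <- p$alpha_mit * (flux_mcu(cc, p) +
                            flux_nclx(cc, p$Ca_mit, p) +
                            flux_mit_leak(p$Ca_mit, cc, p))
  pmf <- flux_pm_leak_pmca(cc, p)
  J_ecs <- p$alpha_pm * (pmf[[1]] + pmf[[2]] + flux_ncx(cc, p) +
                           flux_vocc(cc, p))

  dmyo <- myosin_rhs(Mp, AMp, AM, cc, p)
  J_cyt <- myosin_ca_flux(dmyo, p)

  dy <- c(
    (J_er + J_mit + J_ecs + J_cyt) / buffer_factor_cyt(cc, p),
    -p$r_ercyt * J_er / buffer_factor_er(ca_er, p),
    ip3_pip2_rhs(ip3, pip2, cc, p),
    dmyo,
    ip3r_rhs(X00, X01, X10, cc, ip3, p),
    ryr_rhs(R10, R11, R01, cc, p),
    -J_ecs,
    J_mit)
  list(dy)
}
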