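# Simulation ----------------------------------------------------------------

default_atol <- function() {
  a <- rep(1e-9, length(.state_names))
  names(a) <- .state_names
  a[c("Mp", "AMp", "AM", "X00", "X01", "X10", "R10", "R11", "R01")] <- 1e-12
  a
}

#' Simulate the calibrated model
#'
#' Integrates the full stiff system with [deSolve::ode()] (default `radau`,
#' an implicit stiffly-accurate Runge-Kutta) at relative tolerance `1e-6` and
#' per-state absolute tolerances (1e-9 uM for concentrations, 1e-12 for
#' gate probabilities). The clearance accumulators are integrated as ODE
#' states so they inherit solver error control. The compiled right-hand
#' side is used; [vsm_rhs()] is the plain-R reference.
#'
#' @param object a [vsm_model()].
#' @param nsim,seed unused (the model is deterministic); kept for the
#'   [stats::simulate()] generic signature.
#' @param ca_mit matrix free calcium for the scenario (uM); default the
#'   calibrated model's value.
#' @param t_max simulation horizon (s).
#' @param output_dt output sampling interval (s).
#' @param alpha named or positional numeric length 3: rescaling factors
#'   `(alpha_er, alpha_mit, alpha_pm)` of the compartment flux aggregates.
#' @param initial initial state; defaults to the calibrated baseline.
#' @param rtol,atol solver tolerances.
#' @param ... passed on to [deSolve::ode()].
#' @return A `vsm_traj` object: data frame of times, states, per-mechanism
#'   fluxes, compartment aggregates, tension fraction and ATP-equivalent
#'   rate, with the scenario parameters attached.
#' @export
simulate.vsm_model <- function(object, nsim = 1, seed = NULL,
                               ca_mit = NULL, t_max = 1800, output_dt = 0.5,
                               alpha = c(er = 1, mit = 1, pm = 1),
                               initial = NULL, rtol = 1e-6,
                               atol = default_atol(), method = "radau",
                               ...) {
  stopifnot(inherits(object, "vsm_model"), t_max > 0, output_dt > 0)
  p <- object$params
  if (!is.null(ca_mit)) p$Ca_mit <- as.numeric(ca_mit)
  alpha <- rep_len(as.numeric(alpha), 3)
  p$alpha_er <- alpha[1]; p$alpha_mit <- alpha[2]; p$alpha_pm <- alpha[3]
  validate_params(p)
  y0 <- if (is.null(initial)) object$baseline else {
    stopifnot(length(initial) == length(.state_names))
    stats::setNames(as.numeric(initial), .state_names)
  }
  times <- seq(0, t_max, by = output_dt)
  out <- deSolve::ode(y = y0, times = times, func = "vsm_derivs",
                      parms = as_parms_vector(p), dllname = "mitovasc",
                      initfunc = "vsm_init", method = method,
                      rtol = rtol, atol = unname(atol),
                      maxsteps = 500000, ...)
  if (attr(out, "istate")[1] < 0)
    stop("integration failed at t = ", max(out[, 1]),
         "; last state: ", paste(signif(out[nrow(out), -1], 4),
                                 collapse = ", "), call. = FALSE)
  traj <- as.data.frame(out)
  names(traj) <- c("time", .state_names)
  fl <- flux_breakdown(traj[.state_names], p)
  traj <- cbind(traj, fl)
  traj$tension <- traj$AMp + traj$AM
  traj$atp_rate <- atp_rate(traj$J_mit_to_cyt, p)
  structure(traj, class = c("vsm_traj", "data.frame"),
            params = p, rtol = rtol, atol = atol)
}

#' @export
print.vsm_traj <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "<vsm_traj> %d samples over %.9g s; Ca_mit = %.3g uM; alpha = (%g, %g, %g)\n",
    nrow(x), max(x$time), p$Ca_mit, p$alpha_er, p$alpha_mit, p$alpha_pm))
  cat(sprintf("  ca_cyt range [%.4g, %.4g] uM; ca_sink(end) = %.4g uM; ca_source(end) = %.4g uM\n",
              min(x$ca_cyt), max(x$ca_cyt),
              x$ca_sink[nrow(x)], x$ca_source[nrow(x)]))
  invisible(x)
}

#' @export
plot.vsm_traj <- function(x, which = c("ca_cyt", "ca_er", "tension",
                                       "J_mit_to_cyt"), ...) {
  op <- graphics::par(mfrow = c(length(which), 1),
                      mar = c(2.5, 4, 0.8, 0.8), mgp = c(1.8, 0.6, 0))
  on.exit(graphics::par(op))
  for (nm in which)
    graphics::plot(x$time, x[[nm]], type = "l", xlab = "time (s)",
                   ylab = nm, ...)
  invisible(x)
}

#' Interpolated clearance accumulators
#'
#' Linear interpolation of the cumulative efflux to the extracellular space
#' (`ca_sink`) and cumulative mitochondrial release (`ca_source`) at
#' arbitrary times inside the trajectory span.
#'
#' @param traj a `vsm_traj`.
#' @param t time(s) in seconds, within the trajectory span.
#' @return data.frame with columns `time`, `ca_sink`, `ca_source` (uM,
#'   cytosol-volume-referenced).
#' @export
cumulative_clearance <- function(traj, t) {
  if (any(t < min(traj$time)) || any(t > max(traj$time)))
    stop("t outside the trajectory span", call. = FALSE)
  data.frame(time = t,
             ca_sink = stats::approx(traj$time, traj$ca_sink, t)$y,
             ca_source = stats::approx(traj$time, traj$ca_source, t)$y)
}

#' Whole-cell mass-balance audit
#'
#' Total calcium bookkeeping along a trajectory: free-plus-bound cytosolic
#' calcium, total ER calcium divided by the ER/cytosol volume ratio,
#' calcium sequestered on phosphorylated cross bridges
#' (`ca_per_myosin * Myo_tot * (Mp + AMp)`, the same stoichiometry used in
#' the myosin flux so the books close), plus the cumulative efflux minus
#' the cumulative mitochondrial supply. The audit value
#' `C(t) - C(0)` would be identically zero for exact integration; its
#' maximum magnitude measures solver drift.
#'
#' @param traj a `vsm_traj`.
#' @return maximum absolute drift (uM) over the trajectory.
#' @export
mass_balance_audit <- function(traj) {
  p <- attr(traj, "params")
  tot <- total_ca_cyt(traj$ca_cyt, p) +
    total_ca_er(traj$ca_er, p) / p$r_ercyt +
    p$ca_per_myosin * p$Myo_tot * (traj$Mp + traj$AMp) +
    traj$ca_sink - traj$ca_source
  max(abs(tot - tot[1]))
}
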