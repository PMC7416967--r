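# Calibrated model object ---------------------------------------------------

#' Calibrate the whole-cell model to its resting state
#'
#' Solves for the free constants so that the physiological resting state —
#' 0.1 uM cytosolic and 500 uM ER free calcium, gates, cross bridges and
#' IP3/PIP2 at their fixed points — is an exact equilibrium of the full
#' system:
#'
#' * `nu_mit_leak`: Ohmic matrix-leak conductance zeroing the total
#'   mitochondrial flux at rest (where the calcium Nernst potential is 0),
#' * `Q_ncx`: NCX prefactor zeroing the summed plasma-membrane fluxes,
#' * `serca_scale`: SERCA density factor zeroing the summed ER fluxes
#'   against the resting IP3R and RyR release.
#'
#' Because each compartment aggregate vanishes at rest, the fixed point is
#' preserved under any `alpha_*` rescaling.
#'
#' @param params a [vsm_params()] object; the calibration constants may be
#'   `NA` (they are computed) or preset (they are kept and only verified).
#' @param ca_cyt_rest,ca_er_rest enforced resting free calcium (uM).
#' @param tol maximum tolerated residual of the full right-hand side at the
#'   assembled resting state (per-state natural units / s).
#' @return An object of class `vsm_model` with elements `params` (the
#'   calibrated parameter set), `baseline` (named resting state vector),
#'   `calibration` (constants, resting IP3/PIP2, residual norm).
#' @examples
#' m <- vsm_model()
#' coef(m)
#' @export
vsm_model <- function(params = vsm_params(), ca_cyt_rest = 0.1,
                      ca_er_rest = 500, tol = 1e-9) {
  p <- params
  c0 <- ca_cyt_rest

  # mitochondrial leak: J_mcu + J_nclx + nu * (E - dPsi) = 0 at cm = c0
  # where E = 0, so nu = (J_mcu + J_nclx) / dPsi
  p_probe <- p
  p_probe$nu_mit_leak <- 0
  j_fixed <- flux_mcu(c0, p_probe) + flux_nclx(c0, c0, p_probe)
  nu_mit_leak <- j_fixed / p$dPsi_m
  if (!is.na(params$nu_mit_leak)) nu_mit_leak <- params$nu_mit_leak
  if (nu_mit_leak <= 0)
    stop("calibrated nu_mit_leak is not positive; check MCU/NCLX constants",
         call. = FALSE)
  p$nu_mit_leak <- nu_mit_leak

  # resting IP3/PIP2 and gate fixed points
  ip <- ip3_steady(c0, p)
  gates <- gate_steady(c0, p, ip3 = ip[["ip3"]])

  # ER balance: serca_scale so that J_serca = -(J_ipr + J_ryr) at rest
  j_rel <- flux_ipr(gates[["X10"]], c0, ca_er_rest, p) +
    flux_ryr(gates[["R10"]], c0, ca_er_rest, p)
  p_unit <- p
  p_unit$serca_scale <- 1
  serca_scale <- -j_rel / flux_serca(c0, ca_er_rest, p_unit)
  if (!is.na(params$serca_scale)) serca_scale <- params$serca_scale
  if (serca_scale <= 0)
    stop("calibrated serca_scale is not positive", call. = FALSE)
  p$serca_scale <- serca_scale

  # plasma membrane balance: Q_ncx so that the four PM fluxes sum to zero
  pm <- flux_pm_leak_pmca(c0, p)
  j_pm_fixed <- flux_vocc(c0, p) + pm[["J_pmca"]] + pm[["J_ecs_leak"]]
  p_unit <- p
  p_unit$Q_ncx <- 1
  Q_ncx <- -j_pm_fixed / flux_ncx(c0, p_unit)
  if (!is.na(params$Q_ncx)) Q_ncx <- params$Q_ncx
  if (Q_ncx <= 0)
    stop("calibrated Q_ncx requires NCX to run inward at rest; check the ",
         "plasma-membrane constants", call. = FALSE)
  p$Q_ncx <- Q_ncx

  myo <- myosin_steady(c0, p)
  baseline <- c(ca_cyt = c0, ca_er = ca_er_rest,
                ip3 = ip[["ip3"]], pip2 = ip[["pip2"]],
                Mp = myo[["Mp"]], AMp = myo[["AMp"]], AM = myo[["AM"]],
                X00 = gates[["X00"]], X01 = gates[["X01"]],
                X10 = gates[["X10"]],
                R10 = gates[["R10"]], R11 = gates[["R11"]],
                R01 = gates[["R01"]],
                ca_sink = 0, ca_source = 0)

  p_rest <- p
  p_rest$Ca_mit <- c0   # residual is defined at the unperturbed rest state
  resid <- unlist(vsm_rhs(0, baseline, p_rest))
  residual_norm <- max(abs(resid))
  if (residual_norm > tol)
    stop("calibration failed: baseline residual ", format(residual_norm),
         " exceeds ", format(tol), call. = FALSE)

  structure(
    list(params = p,
         baseline = baseline,
         calibration = list(nu_mit_leak = nu_mit_leak, Q_ncx = Q_ncx,
                            serca_scale = serca_scale,
                            ip3_ss = ip[["ip3"]], pip2_ss = ip[["pip2"]],
                            ca_cyt_rest = c0, ca_er_rest = ca_er_rest,
                            residual_norm = residual_norm)),
    class = "vsm_model")
}

#' @export
print.vsm_model <- function(x, ...) {
  cal <- x$calibration
  cat("Whole-cell VSM calcium model, calibrated to rest\n")
  cat(sprintf("  resting [Ca]_cyt %.3g uM, [Ca]_er %.4g uM, [Ca]_mit %.3g uM\n",
              cal$ca_cyt_rest, cal$ca_er_rest, x$params$Ca_mit))
  cat(sprintf("  nu_mit_leak = %.4g uM/(s mV), Q_ncx = %.4g uM/s, serca_scale = %.4g\n",
              cal$nu_mit_leak, cal$Q_ncx, cal$serca_scale))
  cat(sprintf("  resting IP3 = %.4g uM; fixed-point residual %.2g\n",
              cal$ip3_ss, cal$residual_norm))
  invisible(x)
}

#' @export
coef.vsm_model <- function(object, ...) {
  with(object$calibration,
       c(nu_mit_leak = nu_mit_leak, Q_ncx = Q_ncx,
         serca_scale = serca_scale, ip3_ss = ip3_ss, pip2_ss = pip2_ss))
}

#' @export
residuals.vsm_model <- function(object, ...) {
  p <- object$params
  p$Ca_mit <- object$calibration$ca_cyt_rest
  r <- unlist(vsm_rhs(0, object$baseline, p))
  names(r) <- .state_names
  r
}

#' @export
summary.vsm_model <- function(object, ...) {
  out <- list(model = object,
              baseline = object$baseline,
              fluxes = flux_breakdown(object$baseline,
                                      within_params(object$params,
                                                    Ca_mit = object$calibration$ca_cyt_rest)))
  class(out) <- "summary.vsm_model"
  out
}

#' @export
print.summary.vsm_model <- function(x, ...) {
  print(x$model)
  cat("\nResting state:\n")
  print(signif(x$baseline, 4))
  cat("\nResting fluxes (uM/s, positive raises cytosolic calcium):\n")
  print(signif(unlist(x$fluxes), 4))
  invisible(x)
}

# small helper: copy a vsm_params with overrides, revalidated
within_params <- function(params, ...) {
  dots <- list(...)
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params[names(dots)] <- lapply(dots, as.numeric)
  validate_params(params)
  params
}
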