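# Rapid-buffer approximation ------------------------------------------------

#' Cytosolic buffering factor
#'
#' Rapid-buffer-approximation divisor for the cytosol: net fluxes into the
#' cytosol change free calcium at rate `J / b_cyt(c)`. Two saturable buffers
#' are carried (calmodulin sites and a lumped "other" buffer), each
#' contributing `K B / (K + c)^2`.
#'
#' @param ca_cyt free cytosolic calcium (uM), scalar or vector, >= 0.
#' @param params a [vsm_params()] object.
#' @return dimensionless factor, always >= 1.
#' @export
buffer_factor_cyt <- function(ca_cyt, params) {
  if (any(ca_cyt < 0)) stop("ca_cyt must be >= 0", call. = FALSE)
  1 + params$K_CaM * params$CaM_tot / (params$K_CaM + ca_cyt)^2 +
    params$K_B * params$B_tot / (params$K_B + ca_cyt)^2
}

#' Total (free + buffer-bound) cytosolic calcium
#'
#' Saturable-buffer total consistent with [buffer_factor_cyt()]:
#' `c + sum_i B_i c / (K_i + c)`, whose derivative in `c` is exactly the
#' buffering factor. Used by the mass-balance audit.
#'
#' @inheritParams buffer_factor_cyt
#' @return total calcium (uM).
#' @export
total_ca_cyt <- function(ca_cyt, params) {
  if (any(ca_cyt < 0)) stop("ca_cyt must be >= 0", call. = FALSE)
  ca_cyt * (1 + params$CaM_tot / (params$K_CaM + ca_cyt) +
              params$B_tot / (params$K_B + ca_cyt))
}

#' ER buffering factor
#'
#' Same rapid-buffer form as the cytosol, for the two luminal buffer classes
#' (a low-affinity high-capacity site and a high-affinity site).
#'
#' @param ca_er free ER calcium (uM), >= 0.
#' @inheritParams buffer_factor_cyt
#' @return dimensionless factor >= 1.
#' @export
buffer_factor_er <- function(ca_er, params) {
  if (any(ca_er < 0)) stop("ca_er must be >= 0", call. = FALSE)
  1 + params$K_CalC * params$CalC_tot / (params$K_CalC + ca_er)^2 +
    params$K_CalP * params$CalP_tot / (params$K_CalP + ca_er)^2
}

#' Total ER calcium (free + bound), per ER volume
#' @inheritParams buffer_factor_er
#' @return total luminal calcium (uM).
#' @export
total_ca_er <- function(ca_er, params) {
  if (any(ca_er < 0)) stop("ca_er must be >= 0", call. = FALSE)
  ca_er * (1 + params$CalC_tot / (params$K_CalC + ca_er) +
             params$CalP_tot / (params$K_CalP + ca_er))
}
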