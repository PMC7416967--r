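# Computational experiments -------------------------------------------------

#' Oscillation-onset scan over matrix calcium
#'
#' Simulates the calibrated model from its baseline for `t_max` seconds at
#' each matrix calcium level on a uniform grid, classifies each run with
#' [detect_oscillation()], and (optionally) bisects between the last
#' quiescent and first oscillatory grid point until the bracket is
#' narrower than `refine_width`.
#'
#' @param model a [vsm_model()].
#' @param ca_mit_range interval (uM) scanned.
#' @param n_points grid size.
#' @param refine bisect the onset bracket.
#' @param refine_width bracket width (uM) at which bisection stops.
#' @param t_max,output_dt simulation settings per grid point.
#' @param ... classification settings passed to [detect_oscillation()].
#' @return list of class `hopf_scan`: `grid` (data.frame with per-point
#'   classification, amplitude, period, envelope and period-averaged
#'   cytosolic calcium) and `threshold` (estimated onset, uM, or `NA` when
#'   the classification does not change over the range).
#' @export
hopf_scan <- function(model, ca_mit_range = c(0.1, 0.5), n_points = 9,
                      refine = TRUE, refine_width = 0.005,
                      t_max = 1800, output_dt = 0.5, ...) {
  stopifnot(length(ca_mit_range) == 2, all(ca_mit_range > 0))
  grid <- seq(ca_mit_range[1], ca_mit_range[2], length.out = n_points)

  classify <- function(cm) {
    traj <- simulate(model, ca_mit = cm, t_max = t_max,
                     output_dt = output_dt)
    osc <- detect_oscillation(traj, ...)
    sel <- traj$time >= osc$transient_end
    list(oscillatory = osc$oscillatory, amplitude = osc$amplitude,
         period = osc$dominant_period,
         ca_min = min(traj$ca_cyt[sel]), ca_max = max(traj$ca_cyt[sel]),
         ca_mean = period_average(traj, "ca_cyt", osc = osc))
  }

  res <- lapply(grid, classify)
  tab <- data.frame(ca_mit = grid,
                    oscillatory = vapply(res, `[[`, TRUE, "oscillatory"),
                    amplitude = vapply(res, `[[`, 1, "amplitude"),
                    period = vapply(res, `[[`, 1, "period"),
                    ca_min = vapply(res, `[[`, 1, "ca_min"),
                    ca_max = vapply(res, `[[`, 1, "ca_max"),
                    ca_mean = vapply(res, `[[`, 1, "ca_mean"))

  threshold <- NA_real_
  first_osc <- match(TRUE, tab$oscillatory)
  if (!is.na(first_osc) && first_osc > 1) {
    lo <- grid[first_osc - 1]; hi <- grid[first_osc]
    if (refine) {
      while (hi - lo > refine_width) {
        mid <- (lo + hi) / 2
        if (classify(mid)$oscillatory) hi <- mid else lo <- mid
      }
    }
    threshold <- (lo + hi) / 2
  }
  structure(list(grid = tab, threshold = threshold,
                 settings = list(t_max = t_max, refine = refine,
                                 refine_width = refine_width)),
            class = "hopf_scan")
}

#' @export
print.hopf_scan <- function(x, ...) {
  cat(sprintf("Oscillation-onset scan: %d grid points over [%g, %g] uM\n",
              nrow(x$grid), min(x$grid$ca_mit), max(x$grid$ca_mit)))
  cat(sprintf("  estimated onset: %s uM\n",
              if (is.na(x$threshold)) "not bracketed" else
                sprintf("%.4f", x$threshold)))
  invisible(x)
}

#' Reference run at elevated matrix calcium
#'
#' The headline scenario: 30 minutes at 0.25 uM matrix free calcium from
#' the calibrated baseline. Reports the trajectory, clearance accumulators,
#' tension range, oscillation summary and the net ATP-equivalent of the
#' mitochondrial flux.
#'
#' @param model a [vsm_model()].
#' @param ca_mit matrix calcium (uM).
#' @param t_max horizon (s).
#' @param ... passed to [simulate.vsm_model()].
#' @return list of class `reference_run`: `trajectory`, `oscillation`,
#'   `clearance` (sink/source at `t_max`), `tension_range`,
#'   `mean_J_mit_to_cyt`, `mean_atp_rate`, `mass_balance_drift`.
#' @export
reference_run <- function(model, ca_mit = 0.25, t_max = 1800, ...) {
  traj <- simulate(model, ca_mit = ca_mit, t_max = t_max, ...)
  osc <- detect_oscillation(traj)
  cl <- cumulative_clearance(traj, t_max)
  structure(list(
    trajectory = traj,
    oscillation = osc,
    clearance = c(ca_sink = cl$ca_sink, ca_source = cl$ca_source),
    tension_range = range(traj$tension),
    mean_J_mit_to_cyt = period_average(traj, "J_mit_to_cyt", osc = osc),
    mean_atp_rate = period_average(traj, "atp_rate", osc = osc),
    mass_balance_drift = mass_balance_audit(traj)),
    class = "reference_run")
}

#' @export
print.reference_run <- function(x, ...) {
  p <- attr(x$trajectory, "params")
  cat(sprintf("Reference run: Ca_mit = %g uM, %g s\n",
              p$Ca_mit, max(x$trajectory$time)))
  cat(sprintf("  expelled to ECS: %.1f uM; released by mitochondria: %.1f uM\n",
              x$clearance[["ca_sink"]], x$clearance[["ca_source"]]))
  cat(sprintf("  tension fraction range: [%.3f, %.3f]\n",
              x$tension_range[1], x$tension_range[2]))
  cat(sprintf("  period-averaged J_mit->cyt: %.4g uM/s (ATP %.4g uM/s)\n",
              x$mean_J_mit_to_cyt, x$mean_atp_rate))
  print(x$oscillation)
  invisible(x)
}

#' Compartment flux-rescaling sweep
#'
#' Rescales the three compartment flux aggregates by factors
#' `alpha_er, alpha_mit, alpha_pm` on a log10-uniform grid over
#' `alpha_range` (the rescaling leaves the calibrated fixed point intact),
#' simulates each cell at elevated matrix calcium, classifies oscillation,
#' and records the period-averaged boundary fluxes over the final analysis
#' window. The headline statistic is the fraction of cells whose
#' period-averaged mitochondria-to-cytosol flux is negative (net re-uptake)
#' at the end of the run.
#'
#' @param model a [vsm_model()].
#' @param points_per_axis grid resolution per alpha axis.
#' @param ca_mit matrix calcium (uM) for every cell.
#' @param alpha_range range of each rescaling factor.
#' @param t_max,output_dt simulation settings per cell.
#' @param ... classification settings for [detect_oscillation()].
#' @return list of class `alpha_sweep`: `grid` (one row per cell:
#'   log10-alphas, oscillatory flag, period-averaged `J_mit_to_cyt` and
#'   `J_ecs_to_cyt`, amplitude, failure flag) and `inward_fraction`.
#' @export
alpha_sweep <- function(model, points_per_axis = 7, ca_mit = 0.25,
                        alpha_range = c(0.1, 10),
                        t_max = 1800, output_dt = 0.5, ...) {
  la <- seq(log10(alpha_range[1]), log10(alpha_range[2]),
            length.out = points_per_axis)
  cells <- expand.grid(log_aer = la, log_amit = la, log_apm = la,
                       KEEP.OUT.ATTRS = FALSE)
  n <- nrow(cells)
  osc <- logical(n); jmit <- jecs <- amp <- rep(NA_real_, n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    a <- 10^unlist(cells[i, ])
    res <- tryCatch({
      traj <- simulate(model, ca_mit = ca_mit, t_max = t_max,
                       output_dt = output_dt, alpha = a)
      o <- detect_oscillation(traj, ...)
      c(osc = o$oscillatory, amp = o$amplitude,
        jmit = period_average(traj, "J_mit_to_cyt", osc = o),
        jecs = period_average(traj, "J_ecs_to_cyt", osc = o))
    }, error = function(e) NULL)
    if (is.null(res)) failed[i] <- TRUE else {
      osc[i] <- res[["osc"]] > 0; amp[i] <- res[["amp"]]
      jmit[i] <- res[["jmit"]]; jecs[i] <- res[["jecs"]]
    }
  }
  grid <- cbind(cells, oscillatory = osc, amplitude = amp,
                J_mit_to_cyt = jmit, J_ecs_to_cyt = jecs, failed = failed)
  structure(list(grid = grid,
                 inward_fraction = mean(jmit[!failed] < 0),
                 settings = list(points_per_axis = points_per_axis,
                                 ca_mit = ca_mit, t_max = t_max)),
            class = "alpha_sweep")
}

#' @export
print.alpha_sweep <- function(x, ...) {
  cat(sprintf("Flux-rescaling sweep: %d cells (%d^3), Ca_mit = %g uM\n",
              nrow(x$grid), x$settings$points_per_axis, x$settings$ca_mit))
  cat(sprintf("  oscillatory cells: %d; failed: %d\n",
              sum(x$grid$oscillatory), sum(x$grid$failed)))
  cat(sprintf("  net-inward mitochondrial flux: %.1f%% of cells\n",
              100 * x$inward_fraction))
  invisible(x)
}

#' Tissue-scale calcium transfer envelope
#'
#' Back-of-envelope accounting for the acute phase: the fraction of
#' extracellular calcium transferred into cells when the ECS concentration
#' drops from `ecs_conc` to `residual_conc` while the ECS volume fraction
#' shrinks by `volume_shrink`, and the effective cytosol-referenced load if
#' the cellular compartment (volume fraction `cell_fraction`) absorbs all
#' of it.
#'
#' @param ecs_conc initial extracellular calcium (uM).
#' @param residual_conc post-wave extracellular calcium (uM).
#' @param volume_shrink factor by which the ECS volume shrinks (0.5 =
#'   halved).
#' @param ecs_fraction,cell_fraction resting tissue volume fractions.
#' @param dilution_factor optional direct dilution factor; when given, the
#'   effective load is `ecs_conc / dilution_factor` instead of the volume
#'   ratio form.
#' @return named numeric: `transfer_pct` (% of initial extracellular
#'   calcium entering cells) and `effective_load` (uM).
#' @export
tissue_envelope <- function(ecs_conc = 1300, residual_conc = 100,
                            volume_shrink = 0.5, ecs_fraction = 0.2,
                            cell_fraction = 0.8, dilution_factor = NULL) {
  if (cell_fraction <= 0) stop("cell_fraction must be > 0", call. = FALSE)
  if (ecs_fraction <= 0 || ecs_fraction + cell_fraction > 1 + 1e-9)
    stop("volume fractions must be positive and sum to at most 1",
         call. = FALSE)
  transfer <- if (ecs_conc == 0) 0 else
    100 * (1 - residual_conc * volume_shrink / ecs_conc)
  load <- if (is.null(dilution_factor))
    ecs_conc * ecs_fraction / cell_fraction
  else ecs_conc / dilution_factor
  c(transfer_pct = transfer, effective_load = load)
}
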