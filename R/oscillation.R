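# Oscillation detection and period averaging --------------------------------

# Periodogram of a uniformly sampled signal: mean removed, Hann tapered,
# zero padded x4 for peak localization.  Returns frequencies (Hz, excluding
# DC) and power.
periodogram <- function(x, dt) {
  x <- x - mean(x)
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  xp <- c(x * w, numeric(3 * n))
  m <- length(xp)
  P <- Mod(stats::fft(xp))^2
  keep <- 2:floor(m / 2)
  list(freq = (keep - 1) / (m * dt), power = P[keep])
}

#' Classify a trajectory as oscillatory or quiescent
#'
#' Discards the initial transient, then measures the half peak-to-trough
#' amplitude of the chosen observable on the analysis window and locates
#' the dominant periodogram peak of the mean-removed signal. The run is
#' classified oscillatory when the amplitude exceeds `amp_threshold`, the
#' dominant peak power exceeds `peak_ratio` times the median spectral
#' power, and the dominant period fits at least twice inside the window
#' (so slow residual drift does not masquerade as a rhythm).
#'
#' The amplitude criterion defaults to 2% of the resting cytosolic calcium
#' (0.002 uM): the study the model reproduces states no classification
#' rule, so the convention is calibrated against its printed oscillation
#' onset in matrix calcium and kept fixed everywhere (see the package
#' vignette).
#'
#' @param traj a `vsm_traj` from [simulate.vsm_model()].
#' @param transient_end time (s) discarded as transient.
#' @param analysis_window length (s) of the window analysed after
#'   `transient_end`; defaults to the remainder of the trajectory.
#' @param observable column analysed (default cytosolic calcium).
#' @param amp_threshold amplitude criterion (uM).
#' @param peak_ratio periodogram dominance criterion.
#' @return list of class `osc_summary`: `oscillatory`, `amplitude` (uM),
#'   `dominant_period` (s or `NA`), `mean_level`, `transient_end`,
#'   `window` (s), `peak_ratio_observed`.
#' @export
detect_oscillation <- function(traj, transient_end = 600,
                               analysis_window = NULL,
                               observable = "ca_cyt",
                               amp_threshold = 0.002, peak_ratio = 10) {
  if (!observable %in% names(traj))
    stop("unknown observable '", observable, "'", call. = FALSE)
  t_end <- max(traj$time)
  if (is.null(analysis_window)) analysis_window <- t_end - transient_end
  if (transient_end + analysis_window > t_end + 1e-9)
    stop("analysis window extends beyond the trajectory", call. = FALSE)
  sel <- traj$time >= transient_end &
    traj$time <= transient_end + analysis_window
  x <- traj[[observable]][sel]
  dt <- stats::median(diff(traj$time[sel]))
  amp <- (max(x) - min(x)) / 2

  period <- NA_real_
  ratio_obs <- 0
  if (amp > 0 && length(x) > 8) {
    pg <- periodogram(x, dt)
    i <- which.max(pg$power)
    ratio_obs <- pg$power[i] / stats::median(pg$power)
    period <- 1 / pg$freq[i]
  }
  osc <- is.finite(period) && amp > amp_threshold &&
    ratio_obs > peak_ratio && period <= analysis_window / 2
  structure(list(oscillatory = osc, amplitude = amp,
                 dominant_period = if (osc) period else NA_real_,
                 mean_level = mean(x), transient_end = transient_end,
                 window = analysis_window, peak_ratio_observed = ratio_obs),
            class = "osc_summary")
}

#' @export
print.osc_summary <- function(x, ...) {
  cat(sprintf("oscillatory: %s  amplitude: %.4g uM  period: %s s\n",
              x$oscillatory, x$amplitude,
              if (is.na(x$dominant_period)) "-" else
                sprintf("%.1f", x$dominant_period)))
  invisible(x)
}

#' Period-averaged observable
#'
#' Time average of a trajectory column over the largest whole number of
#' dominant periods that fits at the end of the analysis window (so the
#' average is unbiased by partial cycles); for quiescent runs, the average
#' over the whole window.
#'
#' @param traj a `vsm_traj`.
#' @param observable column name.
#' @param osc optional [detect_oscillation()] result for `traj` (recomputed
#'   if missing).
#' @param ... passed to [detect_oscillation()] when `osc` is missing.
#' @return the period-averaged value.
#' @export
period_average <- function(traj, observable, osc = NULL, ...) {
  if (!observable %in% names(traj))
    stop("unknown observable '", observable, "'", call. = FALSE)
  if (is.null(osc)) osc <- detect_oscillation(traj, ...)
  t_end <- max(traj$time)
  t_from <- osc$transient_end
  if (isTRUE(osc$oscillatory) && is.finite(osc$dominant_period)) {
    ncyc <- floor(osc$window / osc$dominant_period)
    if (ncyc >= 1) t_from <- t_end - ncyc * osc$dominant_period
  }
  sel <- traj$time >= t_from
  mean(traj[[observable]][sel])
}
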