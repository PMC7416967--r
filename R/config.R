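# Configuration and serialization -------------------------------------------

#' Load a run configuration
#'
#' Reads a YAML configuration with two optional sections: `parameters`
#' (named overrides of [vsm_params()] fields) and `scenario`
#' (`ca_mit`, `t_max`, `output_dt`, `alpha_er`, `alpha_mit`, `alpha_pm`).
#' Unknown keys in either section are rejected. An empty or missing file
#' yields pure defaults.
#'
#' @param path YAML file; `NULL` for defaults.
#' @return list of class `vsm_config` with `params` (a [vsm_params()]
#'   object), `scenario` and `overridden` (names of overridden parameters).
#' @export
load_config <- function(path = NULL) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read configuration files",
           call. = FALSE)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
  }
  unknown <- setdiff(names(cfg), c("parameters", "scenario"))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pover <- cfg$parameters %||% list()
  params <- do.call(vsm_params, lapply(pover, as.numeric))
  scen_defaults <- list(ca_mit = params$Ca_mit, t_max = 1800,
                        output_dt = 0.5, alpha_er = params$alpha_er,
                        alpha_mit = params$alpha_mit,
                        alpha_pm = params$alpha_pm)
  sover <- cfg$scenario %||% list()
  unknown <- setdiff(names(sover), names(scen_defaults))
  if (length(unknown))
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  scen <- utils::modifyList(scen_defaults, lapply(sover, as.numeric))
  structure(list(params = params, scenario = scen,
                 overridden = names(pover)),
            class = "vsm_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory as tidy CSV
#'
#' One row per output time, one column per state/flux/derived quantity,
#' with a unit row under the header.
#'
#' @param traj a `vsm_traj`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  units <- vapply(names(traj), function(nm) {
    if (nm == "time") "s"
    else if (nm %in% c("Mp", "AMp", "AM", "X00", "X01", "X10",
                       "R10", "R11", "R01", "tension")) "fraction"
    else if (startsWith(nm, "J_") || nm == "atp_rate") "uM/s"
    else "uM"
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(traj), collapse = ","), con)
  writeLines(paste(units, collapse = ","), con)
  utils::write.table(as.data.frame(traj), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a calibration / experiment summary as JSON
#'
#' @param x a `vsm_model`, `hopf_scan`, `reference_run` or `alpha_sweep`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  payload <- if (inherits(x, "vsm_model")) {
    list(kind = "calibration", calibration = x$calibration,
         baseline = as.list(x$baseline),
         parameters = unclass(x$params))
  } else if (inherits(x, "hopf_scan")) {
    list(kind = "hopf_scan", threshold = x$threshold, grid = x$grid,
         settings = x$settings)
  } else if (inherits(x, "reference_run")) {
    list(kind = "reference_run",
         clearance = as.list(x$clearance),
         tension_range = x$tension_range,
         mean_J_mit_to_cyt = x$mean_J_mit_to_cyt,
         mean_atp_rate = x$mean_atp_rate,
         mass_balance_drift = x$mass_balance_drift,
         oscillation = unclass(x$oscillation))
  } else if (inherits(x, "alpha_sweep")) {
    list(kind = "alpha_sweep", inward_fraction = x$inward_fraction,
         settings = x$settings, grid = x$grid)
  } else stop("no JSON writer for class ", paste(class(x), collapse = "/"),
              call. = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
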