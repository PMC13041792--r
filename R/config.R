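SYSTEM_KINDS <- c("Cart", "Portable", "Renishaw", "MANTIS", "custom")

## instrument families that deliver calibrated, response-corrected spectra
default_requires <- function(system) {
  if (system == "Renishaw") list(calibration = FALSE, src = FALSE)
  else list(calibration = TRUE, src = TRUE)
}

#' System-level instrument configuration
#'
#' Describes an acquisition system and, crucially, whether its spectra need
#' X-axis calibration and spectral response correction before the pipeline.
#' Renishaw-class systems export calibrated spectra, so both default to
#' `FALSE` there; the open `"custom"` kind requires both flags explicitly.
#'
#' @param system One of `"Cart"`, `"Portable"`, `"Renishaw"`, `"MANTIS"`,
#'   `"custom"`.
#' @param excitation_wavelength_nm Laser wavelength, nm.
#' @param detector,probe Free-text hardware labels.
#' @param spectral_range Length-2 numeric, cm-1.
#' @param ccd_x,ccd_y Detector dimensions (`ccd_x >= 2`).
#' @param requires_calibration,requires_src Stage-activation flags; default
#'   by system kind.
#' @return A `system_config` object.
#' @export
system_config <- function(system, excitation_wavelength_nm = 785,
                          detector = "unspecified", probe = "unspecified",
                          spectral_range = c(100, 3400),
                          ccd_x = 1340L, ccd_y = 100L,
                          requires_calibration = NULL, requires_src = NULL) {
  system <- match.arg(system, SYSTEM_KINDS)
  defs <- default_requires(system)
  if (is.null(requires_calibration)) {
    if (system == "custom")
      stop("custom systems must state requires_calibration explicitly",
           call. = FALSE)
    requires_calibration <- defs$calibration
  }
  if (is.null(requires_src)) {
    if (system == "custom")
      stop("custom systems must state requires_src explicitly", call. = FALSE)
    requires_src <- defs$src
  }
  if (excitation_wavelength_nm <= 0)
    stop("excitation_wavelength_nm must be positive", call. = FALSE)
  spectral_range <- as.numeric(spectral_range)
  if (length(spectral_range) != 2L || spectral_range[1] >= spectral_range[2])
    stop("spectral_range must be an increasing length-2 interval", call. = FALSE)
  ccd_x <- as.integer(ccd_x); ccd_y <- as.integer(ccd_y)
  if (is.na(ccd_x) || ccd_x < 2L) stop("ccd_x must be at least 2", call. = FALSE)
  if (is.na(ccd_y) || ccd_y < 1L) stop("ccd_y must be positive", call. = FALSE)
  structure(list(system = system,
                 excitation_wavelength_nm = as.numeric(excitation_wavelength_nm),
                 detector = detector, probe = probe,
                 spectral_range = spectral_range,
                 ccd_x = ccd_x, ccd_y = ccd_y,
                 requires_calibration = isTRUE(requires_calibration),
                 requires_src = isTRUE(requires_src)),
            class = "system_config")
}

SYSTEM_KEYS <- c("system", "excitation_wavelength_nm", "detector", "probe",
                 "spectral_range", "ccd_x", "ccd_y", "requires_calibration",
                 "requires_src")
PIPELINE_KEYS <- c("truncate_start", "truncate_stop", "bin_width", "smoothing",
                   "fbs", "normalization", "apply_src", "cosmic_ray")

check_keys <- function(keys, allowed, what, path) {
  unknown <- setdiff(keys, allowed)
  if (length(unknown) > 0L)
    stop(sprintf("%s '%s': unknown key(s): %s", what, path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
}

#' Load / save the system configuration (config.json)
#'
#' The schema is strict: unknown keys are errors (no silent defaulting), and
#' `system` plus `excitation_wavelength_nm` are required. All other keys
#' fall back to the documented [system_config()] defaults.
#'
#' @param path JSON file path.
#' @return [load_system_config()] returns a [system_config()].
#' @export
load_system_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such config file: '%s'", path), call. = FALSE)
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys(names(v), SYSTEM_KEYS, "system config", path)
  required <- c("system", "excitation_wavelength_nm")
  miss <- setdiff(required, names(v))
  if (length(miss) > 0L)
    stop(sprintf("system config '%s': missing required key(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  args <- v[intersect(SYSTEM_KEYS, names(v))]
  do.call(system_config, args)
}

#' @rdname load_system_config
#' @param cfg A [system_config()].
#' @export
save_system_config <- function(path, cfg) {
  if (!inherits(cfg, "system_config"))
    stop("cfg must be a system_config", call. = FALSE)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load / save the pipeline configuration (preprocessing.json)
#'
#' Strict schema over exactly the [pipeline_config()] fields; unknown keys
#' (including misspellings) are errors. Absent keys take the documented
#' defaults (truncation 900-1700 cm-1, bin width 3.5 cm-1, smoothing none,
#' fifth-order background, mean normalization).
#'
#' @param path JSON file path.
#' @return [load_pipeline_config()] returns a [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such config file: '%s'", path), call. = FALSE)
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys(names(v), PIPELINE_KEYS, "pipeline config", path)
  if (!is.null(v$smoothing))
    check_keys(names(v$smoothing), c("method", "window", "polyorder"),
               "pipeline config (smoothing)", path)
  if (!is.null(v$fbs))
    check_keys(names(v$fbs), c("poly_order", "max_iterations", "tolerance"),
               "pipeline config (fbs)", path)
  defaults <- pipeline_config()
  for (k in c("smoothing", "fbs"))
    if (!is.null(v[[k]]))
      v[[k]] <- utils::modifyList(defaults[[k]], as.list(v[[k]]))
  args <- utils::modifyList(unclass(defaults), v[!vapply(v, is.null, logical(1))])
  do.call(pipeline_config, args)
}

#' @rdname load_pipeline_config
#' @param cfg A [pipeline_config()].
#' @export
save_pipeline_config <- function(path, cfg) {
  if (!inherits(cfg, "pipeline_config"))
    stop("cfg must be a pipeline_config", call. = FALSE)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Resolve the execution path for an instrument/pipeline pairing
#'
#' The system configuration decides whether calibration and response
#' correction run; the stage sequence itself is immutable. P2 is active only
#' when the system requires response correction *and* the pipeline enables
#' it; P6 is active unless smoothing is `"none"`; P3 is always a recorded
#' no-op.
#'
#' @param sys_cfg A [system_config()].
#' @param pipe_cfg A [pipeline_config()].
#' @return An `execution_path`: `list(run_calibration, run_src, stages)`
#'   where `stages` is a data frame with columns `stage` and `active`.
#' @export
resolve_execution_path <- function(sys_cfg, pipe_cfg) {
  if (!inherits(sys_cfg, "system_config"))
    stop("sys_cfg must be a system_config", call. = FALSE)
  if (!inherits(pipe_cfg, "pipeline_config"))
    stop("pipe_cfg must be a pipeline_config", call. = FALSE)
  run_src <- sys_cfg$requires_src
  active <- c(TRUE,                                    # P1
              run_src && pipe_cfg$apply_src,           # P2
              TRUE,                                    # P3 (noop)
              TRUE, TRUE,                              # P4, P5
              pipe_cfg$smoothing$method != "none",     # P6
              TRUE, TRUE)                              # P7, P8
  structure(list(run_calibration = sys_cfg$requires_calibration,
                 run_src = run_src,
                 stages = data.frame(stage = PIPELINE_STAGES, active = active)),
            class = "execution_path")
}
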