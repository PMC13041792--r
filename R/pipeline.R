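PIPELINE_STAGES <- c("P1", "P2", "P3", "P4", "P5", "P6", "P7", "P8")

#' The fixed preprocessing stage sequence
#'
#' Eight stages applied in immutable order: P1 baseline shift, P2 spectral
#' response correction, P3 cosmic-ray placeholder, P4 truncation, P5
#' binning, P6 smoothing, P7 fluorescence background subtraction, P8
#' normalization. The order is not configurable; configurations only toggle
#' whether P2 and P6 act.
#'
#' @return Character vector `c("P1", ..., "P8")`.
#' @export
pipeline_stages <- function() PIPELINE_STAGES

#' Pipeline configuration
#'
#' Declarative parameterization of the eight preprocessing stages. Defaults
#' follow the fingerprint-region conventions: truncation to 900-1700 cm-1,
#' 3.5 cm-1 bins, no smoothing, fifth-order iterative-polynomial background
#' subtraction, mean normalization.
#'
#' @param truncate_start,truncate_stop Truncation interval (cm-1), closed on
#'   both ends; `truncate_start < truncate_stop`.
#' @param bin_width Bin width (cm-1), > 0.
#' @param smoothing `list(method, window, polyorder)`; method one of
#'   `"savgol"`, `"moving_average"`, `"median"`, `"none"`.
#' @param fbs `list(poly_order, max_iterations, tolerance)` for the
#'   fluorescence background iteration.
#' @param normalization `"mean"`, `"area"` or `"max"`.
#' @param apply_src Whether P2 applies the response correction factor.
#' @param cosmic_ray Only `"none"` (P3 is a structural placeholder).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(truncate_start = 900, truncate_stop = 1700,
                            bin_width = 3.5,
                            smoothing = list(method = "none", window = NULL,
                                             polyorder = NULL),
                            fbs = list(poly_order = 5L, max_iterations = 100L,
                                       tolerance = 1e-4),
                            normalization = "mean", apply_src = TRUE,
                            cosmic_ray = "none") {
  if (!is.numeric(truncate_start) || !is.numeric(truncate_stop) ||
      truncate_start >= truncate_stop)
    stop("truncate_start must be less than truncate_stop", call. = FALSE)
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be positive", call. = FALSE)
  if (!is.list(smoothing) || is.null(smoothing$method))
    stop("smoothing must be a list with at least a method", call. = FALSE)
  smoothing$method <- match.arg(smoothing$method,
                                c("savgol", "moving_average", "median", "none"))
  if (!is.list(fbs) || any(!c("poly_order", "max_iterations", "tolerance")
                           %in% names(fbs)))
    stop("fbs must list poly_order, max_iterations and tolerance", call. = FALSE)
  if (fbs$poly_order < 0) stop("fbs poly_order must be >= 0", call. = FALSE)
  if (fbs$max_iterations < 1) stop("fbs max_iterations must be >= 1", call. = FALSE)
  if (fbs$tolerance < 0) stop("fbs tolerance must be >= 0", call. = FALSE)
  normalization <- match.arg(normalization, c("mean", "area", "max"))
  cosmic_ray <- match.arg(cosmic_ray, "none")
  sm <- list(method = smoothing$method)
  if (!is.null(smoothing$window)) sm$window <- as.integer(smoothing$window)
  if (!is.null(smoothing$polyorder))
    sm$polyorder <- as.integer(smoothing$polyorder)
  structure(list(truncate_start = as.numeric(truncate_start),
                 truncate_stop = as.numeric(truncate_stop),
                 bin_width = as.numeric(bin_width),
                 smoothing = sm,
                 fbs = list(poly_order = as.integer(fbs$poly_order),
                            max_iterations = as.integer(fbs$max_iterations),
                            tolerance = as.numeric(fbs$tolerance)),
                 normalization = normalization,
                 apply_src = isTRUE(apply_src),
                 cosmic_ray = cosmic_ray),
            class = "pipeline_config")
}

#' P1: shift the electronic baseline to zero
#'
#' Subtracts the minimum intensity, so the output minimum is exactly zero.
#'
#' @param s A `raman_spectrum`.
#' @return The shifted spectrum.
#' @export
p1_baseline_subtract <- function(s) {
  stopifnot_spectrum(s)
  with_intensity(s, s$intensity - min(s$intensity))
}

#' P2: apply the spectral response correction factor
#'
#' Multiplies intensities by the correction factor resampled onto the
#' spectrum axis. With `apply = FALSE` the spectrum passes through
#' bit-identically (the bypass used for instruments that deliver corrected
#' spectra).
#'
#' @param s A `raman_spectrum`.
#' @param cf A [correction_factor()] spanning the spectrum axis, or `NULL`.
#' @param apply Whether to apply the correction.
#' @return The corrected (or untouched) spectrum.
#' @export
p2_apply_src <- function(s, cf, apply = TRUE) {
  stopifnot_spectrum(s)
  if (!apply) return(s)
  if (is.null(cf))
    stop("configuration error: P2 is active but no correction factor was supplied",
         call. = FALSE)
  res <- resample_factor(cf, s$axis)
  with_intensity(s, s$intensity * res$factor)
}

#' P3: cosmic-ray handling placeholder
#'
#' A reserved stage kept so the pipeline structure stays fixed while
#' cosmic-ray removal algorithms remain future work: the spectrum passes
#' through bit-identically and the stage is recorded as an executed no-op.
#'
#' @param s A `raman_spectrum`.
#' @return `s`, unchanged.
#' @export
p3_cosmic_ray <- function(s) {
  stopifnot_spectrum(s)
  s
}

#' P4: truncate to a wavenumber range
#'
#' Keeps exactly the points with `start <= axis <= stop` (closed interval).
#'
#' @param s A `raman_spectrum`.
#' @param start,stop Interval bounds (cm-1).
#' @return The truncated spectrum.
#' @export
p4_truncate <- function(s, start = 900, stop = 1700) {
  stopifnot_spectrum(s)
  keep <- s$axis >= start & s$axis <= stop
  if (sum(keep) < 2L)
    stop(sprintf("empty range: fewer than 2 axis points inside [%g, %g]",
                 start, stop), call. = FALSE)
  raman_spectrum(s$axis[keep], s$intensity[keep], s$axis_kind)
}

#' P5: bin onto a uniform wavenumber grid
#'
#' Half-open bins `[v0 + k*w, v0 + (k+1)*w)` anchored at the first axis
#' value; each output intensity is the arithmetic mean of its members and
#' the output axis holds the bin centers `v0 + (k + 0.5)*w`. A trailing
#' partial bin is kept if non-empty; an empty interior bin (input grid
#' coarser than the bin width) is an error.
#'
#' @param s A `raman_spectrum`.
#' @param bin_width Bin width (cm-1), > 0.
#' @return The binned spectrum.
#' @export
p5_bin <- function(s, bin_width = 3.5) {
  stopifnot_spectrum(s)
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  v0 <- s$axis[1]
  k <- floor((s$axis - v0) / bin_width)
  present <- sort(unique(k))
  expected <- 0:max(k)
  missing <- setdiff(expected, present)
  if (length(missing) > 0L)
    stop(sprintf("binning error: bin %d ([%g, %g) cm-1) is empty; input grid is coarser than the bin width",
                 missing[1], v0 + missing[1] * bin_width,
                 v0 + (missing[1] + 1) * bin_width), call. = FALSE)
  means <- vapply(split(s$intensity, k), mean, numeric(1))
  centers <- v0 + (expected + 0.5) * bin_width
  raman_spectrum(centers, means, s$axis_kind)
}

#' P6: noise smoothing
#'
#' One of Savitzky-Golay, centered moving average (edge windows shrink
#' symmetrically) or running median; `method = "none"` passes the spectrum
#' through bit-identically.
#'
#' @param s A `raman_spectrum`.
#' @param method `"savgol"`, `"moving_average"`, `"median"` or `"none"`.
#' @param window Odd window length, >= 3.
#' @param polyorder Savitzky-Golay polynomial order (< window).
#' @return The smoothed spectrum.
#' @export
p6_smooth <- function(s, method = "none", window = NULL, polyorder = NULL) {
  stopifnot_spectrum(s)
  if (method == "none") return(s)
  with_intensity(s, smooth_intensity(s$intensity, method, window, polyorder))
}

#' P7: iterative-polynomial fluorescence background subtraction
#'
#' Modpoly-style lower-envelope estimation: starting from the spectrum, a
#' polynomial of the requested order is fitted by least squares and the
#' working curve is replaced by the pointwise minimum of itself and the
#' fit. Iteration stops when the sup-norm change falls below
#' `tolerance * (max(s) - min(s))` or after `max_iterations`. The final fit
#' is the baseline, which is subtracted from the input.
#'
#' The axis is mapped to `[-1, 1]` inside the fits for conditioning; this is
#' invisible in the outputs.
#'
#' @param s A `raman_spectrum`.
#' @param poly_order Baseline polynomial order (>= 0, < number of points).
#' @param max_iterations Iteration cap (>= 1).
#' @param tolerance Relative sup-norm convergence threshold.
#' @return `list(spectrum, baseline, iterations_used)`: the
#'   background-subtracted spectrum, the baseline as a spectrum, and the
#'   number of iterations performed.
#' @export
p7_fluorescence_subtract <- function(s, poly_order = 5L, max_iterations = 100L,
                                     tolerance = 1e-4) {
  stopifnot_spectrum(s)
  n <- length(s$axis)
  if (poly_order >= n)
    stop("fbs poly_order must be smaller than the number of points", call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  scale <- diff(range(s$intensity))
  thresh <- tolerance * if (scale > 0) scale else 1
  working <- s$intensity
  fit_vals <- working
  iterations <- 0L
  for (t in seq_len(max_iterations)) {
    iterations <- t
    fit_vals <- polyval_asc(polyfit_asc(s$axis, working, poly_order), s$axis)
    updated <- pmin(working, fit_vals)
    delta <- max(abs(updated - working))
    working <- updated
    if (delta <= thresh) break
  }
  list(spectrum = with_intensity(s, s$intensity - fit_vals),
       baseline = with_intensity(s, fit_vals),
       iterations_used = iterations)
}

#' P8: normalization
#'
#' `"mean"` divides by the arithmetic mean (output mean is 1), `"area"` by
#' the trapezoidal integral over the axis, `"max"` by the maximum (output
#' max is 1).
#'
#' @param s A `raman_spectrum`.
#' @param method `"mean"`, `"area"` or `"max"`.
#' @return The normalized spectrum.
#' @export
p8_normalize <- function(s, method = "mean") {
  stopifnot_spectrum(s)
  method <- match.arg(method, c("mean", "area", "max"))
  denom <- switch(method,
    mean = mean(s$intensity),
    area = sum(diff(s$axis) *
               (s$intensity[-1] + s$intensity[-length(s$intensity)]) / 2),
    max = max(s$intensity))
  if (denom == 0)
    stop(sprintf("normalization error: %s of the spectrum is zero", method),
         call. = FALSE)
  with_intensity(s, s$intensity / denom)
}

#' Run the full P1-P8 preprocessing chain
#'
#' Applies every stage in fixed order, honouring the P2/P6 skip flags, and
#' records one provenance entry per stage -- including skipped and no-op
#' stages -- with the parameters used and content hashes of the stage input
#' and output.
#'
#' @param s A `raman_spectrum` with `axis_kind = "raman_shift"` (calibration
#'   is applied upstream).
#' @param cfg A [pipeline_config()].
#' @param cf A [correction_factor()] or `NULL`.
#' @param apply_src Effective P2 switch; defaults to `cfg$apply_src`. The
#'   workflow layer lowers it when the system configuration says the
#'   instrument needs no response correction.
#' @return `list(spectrum, provenance)`; `provenance` is a
#'   [provenance_log()] whose entries cover P1..P8 in order.
#' @export
run_pipeline <- function(s, cfg, cf = NULL, apply_src = cfg$apply_src) {
  stopifnot_spectrum(s)
  if (!inherits(cfg, "pipeline_config"))
    stop("cfg must be a pipeline_config", call. = FALSE)
  if (s$axis_kind != "raman_shift")
    stop("run_pipeline expects a Raman-shift axis; apply calibration first",
         call. = FALSE)
  entries <- list()
  cur <- s
  step <- function(stage, op, params, status, fn) {
    in_hash <- spectrum_hash(cur)
    out <- withCallingHandlers(
      tryCatch(fn(cur), error = function(e)
        stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)),
      warning = function(w) w)
    entries[[length(entries) + 1L]] <<- list(
      stage = stage, operation = op, parameters = params, status = status,
      input_hash = in_hash, output_hash = spectrum_hash(out),
      timestamp = iso_timestamp())
    cur <<- out
  }
  step("P1", "baseline_subtract", list(), "applied", p1_baseline_subtract)
  do_src <- isTRUE(apply_src)
  step("P2", "apply_src", list(apply = do_src),
       if (do_src) "applied" else "skipped",
       function(x) p2_apply_src(x, cf, do_src))
  step("P3", "cosmic_ray", list(method = cfg$cosmic_ray), "noop", p3_cosmic_ray)
  step("P4", "truncate",
       list(start = cfg$truncate_start, stop = cfg$truncate_stop), "applied",
       function(x) p4_truncate(x, cfg$truncate_start, cfg$truncate_stop))
  step("P5", "bin", list(bin_width = cfg$bin_width), "applied",
       function(x) p5_bin(x, cfg$bin_width))
  sm <- cfg$smoothing
  step("P6", "smooth", sm, if (sm$method == "none") "skipped" else "applied",
       function(x) p6_smooth(x, sm$method, sm$window, sm$polyorder))
  fbs_out <- NULL
  step("P7", "fluorescence_subtract", cfg$fbs, "applied", function(x) {
    fbs_out <<- p7_fluorescence_subtract(x, cfg$fbs$poly_order,
                                         cfg$fbs$max_iterations,
                                         cfg$fbs$tolerance)
    fbs_out$spectrum
  })
  entries[[7L]]$parameters$iterations_used <- fbs_out$iterations_used
  step("P8", "normalize", list(method = cfg$normalization), "applied",
       function(x) p8_normalize(x, cfg$normalization))
  log <- provenance_log(entries, pipeline_config = cfg,
                        correction_factor = if (do_src) cf else NULL,
                        input_hash = spectrum_hash(s),
                        output_hash = spectrum_hash(cur))
  list(spectrum = cur, provenance = log)
}
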