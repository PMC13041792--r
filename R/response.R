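#' Convert Raman shift to scattered wavelength
#'
#' `lambda = 1e7 / (1e7 / laser_wavelength_nm - delta)` nm. The inverse of
#' the Raman-shift construction: a zero shift maps back to the laser line.
#'
#' @param delta Raman shift(s), cm-1.
#' @param laser_wavelength_nm Excitation wavelength, nm.
#' @return Scattered wavelength(s) in nm.
#' @export
raman_shift_to_wavelength <- function(delta, laser_wavelength_nm) {
  if (laser_wavelength_nm <= 0)
    stop("laser_wavelength_nm must be positive", call. = FALSE)
  denom <- 1e7 / laser_wavelength_nm - delta
  if (any(denom <= 0))
    stop("domain error: 1e7/laser - delta must be positive", call. = FALSE)
  1e7 / denom
}

#' Manufacturer radiance table
#'
#' Tabulated reference radiance of a calibrated broadband (white-light)
#' source versus wavelength, as supplied by the lamp manufacturer.
#'
#' @param wavelength Strictly increasing wavelengths, nm.
#' @param radiance Strictly positive relative radiance values.
#' @return A `radiance_table` object.
#' @export
radiance_table <- function(wavelength, radiance) {
  wavelength <- as.numeric(wavelength)
  radiance <- as.numeric(radiance)
  if (length(wavelength) != length(radiance))
    stop("wavelength and radiance must have equal length", call. = FALSE)
  if (is.unsorted(wavelength, strictly = TRUE))
    stop("radiance table wavelengths must be strictly increasing", call. = FALSE)
  if (any(!is.finite(radiance)) || any(radiance <= 0))
    stop("radiance values must be finite and positive", call. = FALSE)
  structure(list(wavelength = wavelength, radiance = radiance),
            class = "radiance_table")
}

#' Read a radiance table from two-column text/CSV
#'
#' @param path File path (wavelength nm, radiance).
#' @return A [radiance_table()].
#' @export
read_radiance_table <- function(path) {
  s <- read_spectrum(path, spectrum_dialect("auto", "axis_then_intensity", 0L))
  radiance_table(s$axis, s$intensity)
}

#' Certified reference material polynomial certificate
#'
#' The luminescence shape of a NIST-style certified fluorescent glass
#' standard, given as a fifth-order polynomial. Different standards define
#' the polynomial in different variables, so the convention is explicit.
#'
#' @param coeffs Exactly 6 coefficients, ascending powers.
#' @param valid_range Length-2 numeric: certified validity interval (cm-1
#'   Raman shift).
#' @param variable_convention `"raman_shift_cm1"` or `"wavelength_nm"`:
#'   the variable in which the quintic is defined.
#' @return An `srm_certificate` object.
#' @export
srm_certificate <- function(coeffs, valid_range,
                            variable_convention = "raman_shift_cm1") {
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) != 6L)
    stop("an SRM certificate has exactly 6 coefficients", call. = FALSE)
  valid_range <- as.numeric(valid_range)
  if (length(valid_range) != 2L || valid_range[1] >= valid_range[2])
    stop("valid_range must be an increasing length-2 interval", call. = FALSE)
  variable_convention <- match.arg(variable_convention,
                                   c("raman_shift_cm1", "wavelength_nm"))
  structure(list(coeffs = coeffs, valid_range = valid_range,
                 variable_convention = variable_convention),
            class = "srm_certificate")
}

#' Read/write an SRM certificate as JSON
#'
#' @param path File path.
#' @return [read_srm_certificate()] returns an [srm_certificate()].
#' @export
read_srm_certificate <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  srm_certificate(v$coeffs, v$valid_range, v$variable_convention)
}

#' @rdname read_srm_certificate
#' @param cert An [srm_certificate()].
#' @export
write_srm_certificate <- function(path, cert) {
  if (!inherits(cert, "srm_certificate"))
    stop("cert must be an srm_certificate", call. = FALSE)
  jsonlite::write_json(unclass(cert), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## smoothing shared by the response-correction pathways and pipeline P6
smooth_intensity <- function(intensity, method, window, polyorder) {
  method <- match.arg(method, c("savgol", "moving_average", "median", "none"))
  if (method == "none") return(intensity)
  n <- length(intensity)
  window <- as.integer(window)
  if (is.na(window) || window %% 2L == 0L || window < 3L || window > n)
    stop("smoothing window must be odd, at least 3 and at most the spectrum length",
         call. = FALSE)
  switch(method,
    savgol = {
      polyorder <- as.integer(polyorder)
      if (is.na(polyorder) || polyorder >= window)
        stop("savgol polyorder must be smaller than the window", call. = FALSE)
      signal::sgolayfilt(intensity, p = polyorder, n = window)
    },
    moving_average = {
      ## centered running mean; windows shrink symmetrically at the edges so
      ## constants remain fixed points
      half <- window %/% 2L
      vapply(seq_len(n), function(i) {
        h <- min(half, i - 1L, n - i)
        mean(intensity[(i - h):(i + h)])
      }, numeric(1))
    },
    median = stats::runmed(intensity, k = window, endrule = "median"))
}

default_smooth_params <- function() {
  list(method = "savgol", window = 15L, polyorder = 3L)
}

#' White-light spectral response correction
#'
#' Computes the multiplicative correction factor from a measured spectrum of
#' a calibrated broadband source: the measured intensity is smoothed, its
#' Raman-shift axis converted to scattered wavelength, a polynomial is
#' fitted to the manufacturer radiance table and evaluated at the converted
#' axis (the "true" profile), both profiles are scaled to 1 at a common
#' centre wavelength, and the factor is their pointwise ratio true/measured.
#'
#' @param measured A `raman_spectrum` (axis_kind `"raman_shift"`) of the
#'   white-light source.
#' @param radiance A [radiance_table()] covering the converted wavelength
#'   span of `measured` (no extrapolation).
#' @param laser_wavelength_nm Excitation wavelength, nm.
#' @param smooth_params `list(method, window, polyorder)` applied to the
#'   measured intensity before the ratio.
#' @param poly_order Order of the polynomial fitted to the radiance table
#'   (default 5).
#' @param center_wavelength_nm Normalization wavelength; default is the
#'   sample nearest the midpoint of the converted axis.
#' @return A [correction_factor()] on the Raman-shift axis of `measured`.
#' @export
white_light_correction <- function(measured, radiance, laser_wavelength_nm,
                                   smooth_params = default_smooth_params(),
                                   poly_order = 5L,
                                   center_wavelength_nm = NULL) {
  stopifnot_spectrum(measured)
  if (!inherits(radiance, "radiance_table"))
    stop("radiance must be a radiance_table", call. = FALSE)
  smoothed <- smooth_intensity(measured$intensity, smooth_params$method,
                               smooth_params$window, smooth_params$polyorder)
  if (any(smoothed <= 0))
    stop("domain error: measured white-light intensity must be positive after smoothing",
         call. = FALSE)
  lam <- raman_shift_to_wavelength(measured$axis, laser_wavelength_nm)
  if (min(lam) < min(radiance$wavelength) || max(lam) > max(radiance$wavelength))
    stop(sprintf("radiance table [%g, %g] nm does not cover the measured span [%g, %g] nm",
                 min(radiance$wavelength), max(radiance$wavelength),
                 min(lam), max(lam)), call. = FALSE)
  if (length(radiance$wavelength) < poly_order + 1L)
    stop("radiance table has fewer rows than polynomial coefficients",
         call. = FALSE)
  fit <- polyfit_asc(radiance$wavelength, radiance$radiance, poly_order)
  true_profile <- polyval_asc(fit, lam)
  if (any(true_profile <= 0))
    stop("fitted radiance profile is non-positive over the measured span",
         call. = FALSE)
  center <- if (is.null(center_wavelength_nm)) mean(range(lam))
            else center_wavelength_nm
  ic <- nearest_index(lam, center)
  meas_n <- smoothed / smoothed[ic]
  true_n <- true_profile / true_profile[ic]
  correction_factor(measured$axis, true_n / meas_n, "raman_shift")
}

#' Certified-reference-material (SRM) response correction
#'
#' The true luminescence profile is the certified quintic evaluated in the
#' certificate's variable convention; true and measured profiles are scaled
#' to 1 at a common centre point and the factor true/measured is smoothed.
#'
#' @param measured A `raman_spectrum` (axis_kind `"raman_shift"`) of the SRM
#'   glass, with axis inside `cert$valid_range`.
#' @param cert An [srm_certificate()].
#' @param smooth_params Post-ratio smoothing parameters
#'   (default Savitzky-Golay, window 15, order 3).
#' @param laser_wavelength_nm Required when the certificate is defined in
#'   wavelength.
#' @param center Optional normalization point in axis units; default is the
#'   sample nearest the axis midpoint.
#' @return A [correction_factor()] on the Raman-shift axis of `measured`.
#' @export
srm_correction <- function(measured, cert,
                           smooth_params = default_smooth_params(),
                           laser_wavelength_nm = NULL, center = NULL) {
  stopifnot_spectrum(measured)
  if (!inherits(cert, "srm_certificate"))
    stop("cert must be an srm_certificate", call. = FALSE)
  ax <- measured$axis
  if (min(ax) < cert$valid_range[1] || max(ax) > cert$valid_range[2])
    stop(sprintf("measured axis [%g, %g] outside certificate valid range [%g, %g]",
                 min(ax), max(ax), cert$valid_range[1], cert$valid_range[2]),
         call. = FALSE)
  if (any(measured$intensity <= 0))
    stop("domain error: measured SRM intensity must be positive", call. = FALSE)
  x <- if (cert$variable_convention == "wavelength_nm") {
    if (is.null(laser_wavelength_nm))
      stop("laser_wavelength_nm is required for a wavelength-convention certificate",
           call. = FALSE)
    raman_shift_to_wavelength(ax, laser_wavelength_nm)
  } else ax
  true_profile <- polyval_asc(cert$coeffs, x)
  if (any(true_profile <= 0))
    stop("certified profile is non-positive over the measured span", call. = FALSE)
  ic <- nearest_index(ax, if (is.null(center)) mean(range(ax)) else center)
  true_n <- true_profile / true_profile[ic]
  meas_n <- measured$intensity / measured$intensity[ic]
  factor <- true_n / meas_n
  factor <- smooth_intensity(factor, smooth_params$method,
                             smooth_params$window, smooth_params$polyorder)
  if (any(factor <= 0))
    stop("correction factor became non-positive after smoothing", call. = FALSE)
  correction_factor(ax, factor, "raman_shift")
}

#' Resample a correction factor onto a new axis
#'
#' Linear interpolation within the factor's span; extrapolation is refused.
#'
#' @param cf A [correction_factor()].
#' @param target_axis Strictly increasing axis within `cf$axis` span.
#' @return A [correction_factor()] on `target_axis`.
#' @export
resample_factor <- function(cf, target_axis) {
  if (!inherits(cf, "correction_factor"))
    stop("cf must be a correction_factor", call. = FALSE)
  target_axis <- as.numeric(target_axis)
  if (min(target_axis) < cf$axis[1] ||
      max(target_axis) > cf$axis[length(cf$axis)])
    stop(sprintf("resampling target [%g, %g] extends beyond the factor span [%g, %g]",
                 min(target_axis), max(target_axis), cf$axis[1],
                 cf$axis[length(cf$axis)]), call. = FALSE)
  vals <- stats::approx(cf$axis, cf$factor, xout = target_axis)$y
  correction_factor(target_axis, vals, cf$axis_unit)
}
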