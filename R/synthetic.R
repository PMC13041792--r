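#' Forward model for synthetic fixtures
#'
#' Emulates the measurement chain of a dispersive Raman spectrometer: a
#' cubic pixel-to-wavenumber dispersion, an excitation laser, peak shapes,
#' a polynomial background, a smooth instrument response gain, additive
#' Gaussian noise and isolated cosmic-ray spikes. Every generator is a
#' deterministic function of the model and its seed.
#'
#' Defaults describe a 785 nm fingerprint-region instrument: a 1340-pixel
#' detector with dispersion `a = (9300, 3.2, -1e-4, 1e-8)` covering absolute
#' wavenumbers that span both bundled reference libraries at 785 nm-class
#' excitation.
#'
#' @param true_coeffs Cubic dispersion coefficients `c(a0..a3)`, ascending
#'   powers of pixel; `a1 > 0` (monotone dispersion).
#' @param laser_wavelength_nm Excitation wavelength, nm.
#' @param n_pixels Detector pixel count.
#' @param peak_shapes List of `list(center, width, height, profile)` used by
#'   [gen_sample_spectrum()]; centers in cm-1 Raman shift.
#' @param baseline_coeffs Polynomial background, ascending powers of the
#'   generator's axis unit (pixels for lamp/acetaminophen spectra, cm-1 for
#'   samples).
#' @param noise_sigma Additive Gaussian noise, counts.
#' @param cosmic_rays List of `list(pixel, amplitude)` spikes.
#' @param response_gain `NULL`, or a function of wavelength (nm) returning a
#'   smooth positive gain.
#' @param peak_width_px,peak_height Shape of lamp/acetaminophen emission
#'   peaks (Gaussian sigma in pixels; apex counts).
#' @param seed Integer seed controlling every random draw.
#' @return A `forward_model` object.
#' @export
forward_model <- function(true_coeffs = c(9300, 3.2, -1e-4, 1e-8),
                          laser_wavelength_nm = 785.142,
                          n_pixels = 1340L,
                          peak_shapes = list(),
                          baseline_coeffs = 0,
                          noise_sigma = 0,
                          cosmic_rays = list(),
                          response_gain = NULL,
                          peak_width_px = 2.5, peak_height = 1000,
                          seed = 1L) {
  if (length(true_coeffs) != 4L)
    stop("true_coeffs must have length 4", call. = FALSE)
  if (true_coeffs[2] <= 0)
    stop("physical dispersion must be monotone: a1 must be positive",
         call. = FALSE)
  n_pixels <- as.integer(n_pixels)
  if (n_pixels < 2L) stop("n_pixels must be at least 2", call. = FALSE)
  p <- seq_len(n_pixels) - 1
  dvdp <- polyval_asc(c(true_coeffs[2], 2 * true_coeffs[3], 3 * true_coeffs[4]), p)
  if (any(dvdp <= 0))
    stop("true_coeffs are not monotone over the detector range", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(list(true_coeffs = as.numeric(true_coeffs),
                 laser_wavelength_nm = as.numeric(laser_wavelength_nm),
                 n_pixels = n_pixels, peak_shapes = peak_shapes,
                 baseline_coeffs = as.numeric(baseline_coeffs),
                 noise_sigma = as.numeric(noise_sigma),
                 cosmic_rays = cosmic_rays, response_gain = response_gain,
                 peak_width_px = as.numeric(peak_width_px),
                 peak_height = as.numeric(peak_height),
                 seed = as.integer(seed)),
            class = "forward_model")
}

peak_profile <- function(x, center, width, height, profile = "gaussian") {
  switch(match.arg(profile, c("gaussian", "lorentzian")),
         gaussian = height * exp(-0.5 * ((x - center) / width)^2),
         lorentzian = height / (1 + ((x - center) / width)^2))
}

## pixel position where the cubic dispersion reaches `target` (bracketed
## root; dispersion monotonicity is validated in forward_model)
dispersion_root <- function(model, target) {
  f <- function(p) evaluate_calibration(model$true_coeffs, p) - target
  lo <- 0; hi <- model$n_pixels - 1
  if (f(lo) > 0 || f(hi) < 0)
    stop(sprintf("generation error: line %g cm-1 lies outside the detector range [%g, %g]",
                 target, evaluate_calibration(model$true_coeffs, lo),
                 evaluate_calibration(model$true_coeffs, hi)), call. = FALSE)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

## shared machinery for pixel-indexed emission fixtures
gen_emission_spectrum <- function(model, targets_abs) {
  p <- seq_len(model$n_pixels) - 1
  truth <- vapply(targets_abs, function(t) dispersion_root(model, t), numeric(1))
  intensity <- polyval_asc(model$baseline_coeffs, p)
  for (ctr in truth)
    intensity <- intensity +
      peak_profile(p, ctr, model$peak_width_px, model$peak_height)
  set.seed(model$seed)
  if (model$noise_sigma > 0)
    intensity <- intensity + stats::rnorm(length(p), 0, model$noise_sigma)
  list(spectrum = raman_spectrum(p, intensity, "pixel"), truth_pixels = truth)
}

#' Generate a synthetic neon-argon lamp spectrum
#'
#' Places Gaussian emission peaks at the pixel positions where the model's
#' cubic dispersion reaches the selected reference lines, on top of the
#' model background and noise. The exact peak positions are returned as
#' ground truth.
#'
#' @param model A [forward_model()].
#' @param library A [ne_ar_library()]-style reference library.
#' @param subset Indices of the lines to emit (default: all that the
#'   detector covers must be requested explicitly; out-of-range lines are a
#'   generation error).
#' @return `list(spectrum, truth_pixels, line_indices)`.
#' @export
gen_lamp_spectrum <- function(model, library = ne_ar_library(),
                              subset = seq_along(library$lines)) {
  if (!inherits(model, "forward_model"))
    stop("model must be a forward_model", call. = FALSE)
  out <- gen_emission_spectrum(model, library$lines[subset])
  out$line_indices <- subset
  out
}

#' Generate a synthetic acetaminophen reference spectrum
#'
#' Peaks are placed at the absolute wavenumbers
#' `1e7 / laser_wavelength_nm - shift` of the certified Raman shifts, so the
#' laser-wavelength estimator can be validated against the generating value.
#'
#' @param model A [forward_model()].
#' @param library An [acetaminophen_library()]-style shift library.
#' @param subset Indices of the shifts to emit.
#' @return `list(spectrum, truth_pixels, shifts)`.
#' @export
gen_acetaminophen_spectrum <- function(model, library = acetaminophen_library(),
                                       subset = seq_along(library$shifts)) {
  if (!inherits(model, "forward_model"))
    stop("model must be a forward_model", call. = FALSE)
  shifts <- library$shifts[subset]
  targets <- 1e7 / model$laser_wavelength_nm - shifts
  out <- gen_emission_spectrum(model, targets)
  out$shifts <- shifts
  out
}

#' Generate a synthetic sample spectrum on the Raman-shift axis
#'
#' Intensity = sum of the model's peak shapes + polynomial fluorescence
#' background (in cm-1) + optional response gain + Gaussian noise + sparse
#' cosmic-ray spikes, on the ascending Raman-shift axis derived from the
#' model's dispersion and laser. All ground-truth components are returned.
#'
#' @param model A [forward_model()]; `peak_shapes` centers in cm-1 and
#'   `baseline_coeffs` in ascending powers of cm-1.
#' @return `list(spectrum, peaks, baseline, gain, noise)` -- the assembled
#'   spectrum and each additive component on the same axis.
#' @export
gen_sample_spectrum <- function(model) {
  if (!inherits(model, "forward_model"))
    stop("model must be a forward_model", call. = FALSE)
  shift <- compute_raman_shift_axis(model$true_coeffs,
                                    model$laser_wavelength_nm, model$n_pixels)
  ord <- order(shift)
  axis <- shift[ord]
  peaks <- rep(0, length(axis))
  for (pk in model$peak_shapes)
    peaks <- peaks + peak_profile(axis, pk$center, pk$width, pk$height,
                                  if (is.null(pk$profile)) "gaussian"
                                  else pk$profile)
  baseline <- polyval_asc(model$baseline_coeffs, axis)
  gain <- if (is.null(model$response_gain)) rep(1, length(axis))
          else model$response_gain(
            raman_shift_to_wavelength(axis, model$laser_wavelength_nm))
  set.seed(model$seed)
  noise <- if (model$noise_sigma > 0)
    stats::rnorm(length(axis), 0, model$noise_sigma) else rep(0, length(axis))
  intensity <- (peaks + baseline) * gain + noise
  for (cr in model$cosmic_rays) {
    i <- nearest_index(axis, cr$position)
    intensity[i] <- intensity[i] + cr$amplitude
  }
  list(spectrum = raman_spectrum(axis, intensity, "raman_shift"),
       peaks = peaks, baseline = baseline, gain = gain, noise = noise)
}

#' Generate a white-light measurement with its radiance table
#'
#' The "true" lamp profile is a smooth positive cubic in wavelength,
#' tabulated as the manufacturer radiance table; the measured spectrum is
#' that profile times the model's response gain, sampled on the model's
#' Raman-shift axis. The gain is returned as ground truth so correction
#' recovery can be checked pointwise.
#'
#' @param model A [forward_model()]; `response_gain` (function of nm) is the
#'   gain to recover, default identity.
#' @param shift_range Raman-shift span (cm-1) of the measured spectrum.
#' @param n_table Rows in the tabulated radiance table.
#' @return `list(measured, radiance, gain, true_profile)`.
#' @export
gen_whitelight_pair <- function(model, shift_range = c(200, 3200),
                                n_table = 201L) {
  if (!inherits(model, "forward_model"))
    stop("model must be a forward_model", call. = FALSE)
  shift <- compute_raman_shift_axis(model$true_coeffs,
                                    model$laser_wavelength_nm, model$n_pixels)
  axis <- sort(shift)
  axis <- axis[axis >= shift_range[1] & axis <= shift_range[2]]
  lam <- raman_shift_to_wavelength(axis, model$laser_wavelength_nm)
  ## smooth positive cubic, increasing over the NIR span of interest
  true_fun <- function(w) {
    u <- (w - 800) / 100
    0.2 + u - 0.3 * u^2 + 0.05 * u^3
  }
  tab_w <- seq(min(lam) - 5, max(lam) + 5, length.out = n_table)
  gain_fun <- if (is.null(model$response_gain)) function(w) rep(1, length(w))
              else model$response_gain
  gain <- gain_fun(lam)
  if (any(gain <= 0))
    stop("response_gain must be strictly positive over the measured span",
         call. = FALSE)
  true_profile <- true_fun(lam)
  measured <- raman_spectrum(axis, true_profile * gain, "raman_shift")
  list(measured = measured,
       radiance = radiance_table(tab_w, true_fun(tab_w)),
       gain = gain, true_profile = true_profile)
}
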