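#' Refine a peak position to sub-pixel precision
#'
#' Smooths the first derivative with a Savitzky-Golay filter, locates the
#' positive-to-negative derivative sign change nearest the user's approximate
#' position, bounds the peak span by the flanking derivative sign changes
#' (clipped to the search window), and returns the intensity centroid
#' `sum(p * I) / sum(I)` over that span.
#'
#' @param spectrum A pixel-indexed `raman_spectrum`.
#' @param approx_pixel Approximate peak position (pixel units).
#' @param sg_window Savitzky-Golay window length (odd, > `sg_order`).
#' @param sg_order Savitzky-Golay polynomial order.
#' @param search_halfwidth Half-width (pixels) of the window searched for the
#'   apex; also clips the centroid span.
#' @return The refined peak position (real-valued pixel).
#' @export
refine_peak <- function(spectrum, approx_pixel, sg_window = 7L, sg_order = 2L,
                        search_halfwidth = 15) {
  stopifnot_spectrum(spectrum)
  ax <- spectrum$axis
  I <- spectrum$intensity
  n <- length(ax)
  if (approx_pixel < ax[1] || approx_pixel > ax[n])
    stop("approx_pixel outside the spectrum axis range", call. = FALSE)
  sg_window <- as.integer(sg_window)
  sg_order <- as.integer(sg_order)
  if (sg_window %% 2L == 0L || sg_window <= sg_order || sg_window > n)
    stop("sg_window must be odd, greater than sg_order and at most the spectrum length",
         call. = FALSE)
  if (diff(range(I)) == 0)
    stop("no peak found: spectrum is flat", call. = FALSE)
  d <- signal::sgolayfilt(I, p = sg_order, n = sg_window, m = 1)
  i0 <- nearest_index(ax, approx_pixel)
  half_idx <- max(1L, round(search_halfwidth / mean(diff(ax))))
  lo <- max(1L, i0 - half_idx)
  hi <- min(n, i0 + half_idx)
  idx <- lo:(hi - 1L)
  crossings <- idx[d[idx] > 0 & d[idx + 1L] <= 0]
  if (length(crossings) == 0L)
    stop(sprintf("no peak found within %g pixels of %g", search_halfwidth,
                 approx_pixel), call. = FALSE)
  apex <- crossings[which.min(abs(crossings - i0))]
  span_lo <- apex
  while (span_lo > lo && d[span_lo - 1L] > 0) span_lo <- span_lo - 1L
  span_hi <- apex + 1L
  while (span_hi < hi && d[span_hi + 1L] < 0) span_hi <- span_hi + 1L
  span <- span_lo:span_hi
  w <- I[span]
  if (sum(w) <= 0)
    stop("no peak found: non-positive intensity mass in peak span", call. = FALSE)
  sum(ax[span] * w) / sum(w)
}

#' Fit the cubic pixel-to-wavenumber map
#'
#' Least-squares fit of a third-order polynomial
#' `vabs(p) = a0 + a1*p + a2*p^2 + a3*p^3` to refined (pixel, absolute
#' wavenumber) pairs. Pixels are centered and scaled internally before the
#' solve; coefficients are returned on the raw pixel basis, ascending powers,
#' with residual diagnostics attached as attributes (`residuals`, `rms`).
#'
#' @param pairs A two-column matrix or data frame: refined pixel, reference
#'   absolute wavenumber (cm-1). At least 4 distinct pixel positions.
#' @return Numeric vector `c(a0, a1, a2, a3)` with fit diagnostics attached.
#' @export
fit_pixel_to_wavenumber <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L)
    stop("pairs must have two columns: pixel, wavenumber", call. = FALSE)
  if (nrow(pairs) < 4L)
    stop("insufficient data: at least 4 (pixel, wavenumber) pairs are required",
         call. = FALSE)
  if (length(unique(pairs[, 1])) < 4L)
    stop("singular fit: fewer than 4 distinct pixel positions", call. = FALSE)
  coeffs <- polyfit_asc(pairs[, 1], pairs[, 2], 3L)
  names(coeffs) <- paste0("a", 0:3)
  coeffs
}

#' Evaluate the pixel-to-wavenumber polynomial
#'
#' @param coeffs `c(a0, a1, a2, a3)` in ascending powers of pixel.
#' @param p Pixel position(s), real-valued.
#' @return Absolute wavenumber(s) in cm-1 (Horner evaluation).
#' @export
evaluate_calibration <- function(coeffs, p) {
  if (length(coeffs) != 4L)
    stop("coeffs must have length 4 (a0..a3)", call. = FALSE)
  polyval_asc(as.numeric(coeffs), p)
}

#' Estimate the excitation laser wavelength from acetaminophen peaks
#'
#' For each matched peak i, the laser wavelength consistent with the
#' calibrated absolute wavenumber and the certified shift is
#' `1e7 / (vabs(p_i) + dshift_ref_i)` nm; the estimate is the arithmetic
#' mean over peaks. Per-peak estimates and their spread (max - min) are
#' attached as attributes.
#'
#' @param coeffs Calibration coefficients `c(a0..a3)`.
#' @param acet_pixels Refined pixel positions of acetaminophen peaks.
#' @param ref_shifts Matched certified Raman shifts (cm-1), same length.
#' @return Estimated laser wavelength in nm, with attributes `per_peak` and
#'   `spread`.
#' @export
estimate_laser_wavelength <- function(coeffs, acet_pixels, ref_shifts) {
  if (length(acet_pixels) == 0L)
    stop("insufficient data: no matched acetaminophen peaks", call. = FALSE)
  if (length(acet_pixels) != length(ref_shifts))
    stop("acet_pixels and ref_shifts must have equal length", call. = FALSE)
  denom <- evaluate_calibration(coeffs, acet_pixels) + ref_shifts
  if (any(denom <= 0))
    stop("domain error: vabs(p) + reference shift must be positive",
         call. = FALSE)
  per_peak <- 1e7 / denom
  structure(mean(per_peak), per_peak = per_peak,
            spread = max(per_peak) - min(per_peak))
}

#' Compute the per-pixel Raman-shift axis
#'
#' `dshift(p) = 1e7 / laser_wavelength_nm - vabs(p)` for p = 0..n_pixels-1,
#' returned in pixel order. Because vabs normally increases with pixel, the
#' shift decreases with pixel; [apply_calibration()] reverses the
#' axis/intensity pairing so spectra end up ascending.
#'
#' @param coeffs Calibration coefficients `c(a0..a3)`.
#' @param laser_wavelength_nm Excitation wavelength (nm), > 0.
#' @param n_pixels Detector pixel count (>= 2).
#' @return Numeric vector of Raman shifts (cm-1), one per pixel.
#' @export
compute_raman_shift_axis <- function(coeffs, laser_wavelength_nm, n_pixels) {
  if (laser_wavelength_nm <= 0)
    stop("laser_wavelength_nm must be positive", call. = FALSE)
  n_pixels <- as.integer(n_pixels)
  if (n_pixels < 2L) stop("n_pixels must be at least 2", call. = FALSE)
  p <- seq_len(n_pixels) - 1
  1e7 / laser_wavelength_nm - evaluate_calibration(coeffs, p)
}

#' Construct a calibration record
#'
#' @param coeffs `c(a0..a3)` on the raw pixel basis.
#' @param laser_wavelength_nm Excitation wavelength (nm).
#' @param n_pixels Detector pixel count.
#' @param selected_peak_indices Indices of the reference-library lines used.
#' @param calibration_datetime ISO-8601 timestamp string (default: now, UTC).
#' @param fit_rms Root-mean-square residual of the cubic fit (cm-1).
#' @return A `calibration_record` with the derived per-pixel
#'   `raman_shift_axis`.
#' @export
calibration_record <- function(coeffs, laser_wavelength_nm, n_pixels,
                               selected_peak_indices = integer(0),
                               calibration_datetime = iso_timestamp(),
                               fit_rms = NA_real_) {
  if (length(coeffs) != 4L) stop("coeffs must have length 4", call. = FALSE)
  if (laser_wavelength_nm <= 0)
    stop("laser_wavelength_nm must be positive", call. = FALSE)
  axis <- compute_raman_shift_axis(coeffs, laser_wavelength_nm, n_pixels)
  structure(list(coeffs = setNames(as.numeric(coeffs), paste0("a", 0:3)),
                 laser_wavelength_nm = as.numeric(laser_wavelength_nm),
                 raman_shift_axis = axis,
                 selected_peak_indices = as.integer(selected_peak_indices),
                 calibration_datetime = calibration_datetime,
                 fit_rms = as.numeric(fit_rms)),
            class = "calibration_record")
}

#' @export
print.calibration_record <- function(x, ...) {
  cat(sprintf(paste0("<calibration_record> %d pixels, laser %.4f nm, ",
                     "a = [%g, %g, %g, %g], %d reference peaks, %s\n"),
              length(x$raman_shift_axis), x$laser_wavelength_nm,
              x$coeffs[1], x$coeffs[2], x$coeffs[3], x$coeffs[4],
              length(x$selected_peak_indices), x$calibration_datetime))
  invisible(x)
}

#' Build a calibration record from a measured lamp spectrum
#'
#' Composes the full X-axis calibration: refine each marked lamp peak, fit
#' the cubic pixel-to-wavenumber map against the matched reference lines,
#' obtain the laser wavelength (directly, or estimated from an acetaminophen
#' spectrum), and derive the per-pixel Raman-shift axis.
#'
#' @param lamp A pixel-indexed `raman_spectrum` of the Ne-Ar lamp.
#' @param library A [ne_ar_library()]-style reference line library.
#' @param line_indices Indices into `library$lines` of the selected lines
#'   (at least 4; a warning is issued below 6).
#' @param approx_pixels Approximate pixel position of each selected line's
#'   peak, same length as `line_indices`.
#' @param laser Either `list(mode = "direct", wavelength_nm = x)` or
#'   `list(mode = "acetaminophen", spectrum = s, approx_pixels = p,
#'   ref_shifts = d)` for Eq.-style estimation from a measured acetaminophen
#'   spectrum.
#' @param n_pixels Detector pixel count (default: lamp length).
#' @param sg_window,sg_order,search_halfwidth Passed to [refine_peak()].
#' @return A [calibration_record()].
#' @export
build_calibration_record <- function(lamp, library, line_indices, approx_pixels,
                                     laser, n_pixels = length(lamp$axis),
                                     sg_window = 7L, sg_order = 2L,
                                     search_halfwidth = 15) {
  stopifnot_spectrum(lamp)
  if (length(line_indices) != length(approx_pixels))
    stop("line_indices and approx_pixels must have equal length", call. = FALSE)
  if (length(line_indices) < 4L)
    stop("insufficient data: at least 4 reference peaks are required",
         call. = FALSE)
  if (length(line_indices) < 6L)
    warning("fewer than 6 reference peaks selected; the cubic fit will be weakly constrained")
  refined <- vapply(approx_pixels, function(p0)
    refine_peak(lamp, p0, sg_window, sg_order, search_halfwidth), numeric(1))
  targets <- library$lines[line_indices]
  coeffs <- fit_pixel_to_wavenumber(cbind(refined, targets))
  lambda <- if (identical(laser$mode, "direct")) {
    as.numeric(laser$wavelength_nm)
  } else if (identical(laser$mode, "acetaminophen")) {
    acet_refined <- vapply(laser$approx_pixels, function(p0)
      refine_peak(laser$spectrum, p0, sg_window, sg_order, search_halfwidth),
      numeric(1))
    as.numeric(estimate_laser_wavelength(coeffs, acet_refined, laser$ref_shifts))
  } else stop("laser$mode must be 'direct' or 'acetaminophen'", call. = FALSE)
  calibration_record(coeffs, lambda, n_pixels,
                     selected_peak_indices = line_indices,
                     fit_rms = attr(coeffs, "rms"))
}

#' Write a calibration record
#'
#' The primary container is a MATLAB level-5 `.mat` file with variables
#' `wavenumber_axis`, `laser_wavelength_nm`, `poly_coeffs` (a0..a3,
#' ascending powers of pixel), `calibration_datetime` (ISO-8601 string) and
#' `selected_peak_indices`; these names are artifact-defined and documented
#' here. A JSON sidecar with identical field names is written when `path`
#' ends in `.json`.
#'
#' @param path Output path (`.mat` or `.json`).
#' @param record A [calibration_record()].
#' @export
write_calibration_record <- function(path, record) {
  if (!inherits(record, "calibration_record"))
    stop("record must be a calibration_record", call. = FALSE)
  fields <- list(wavenumber_axis = record$raman_shift_axis,
                 laser_wavelength_nm = record$laser_wavelength_nm,
                 poly_coeffs = unname(record$coeffs),
                 calibration_datetime = record$calibration_datetime,
                 selected_peak_indices = as.numeric(record$selected_peak_indices),
                 fit_rms = record$fit_rms)
  if (is.na(fields$fit_rms)) fields$fit_rms <- NULL
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  } else {
    mat5_write(path, fields)
  }
  invisible(path)
}

#' Read a calibration record written by [write_calibration_record()]
#'
#' @param path Path to a `.mat` or `.json` record.
#' @return A [calibration_record()].
#' @export
read_calibration_record <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such calibration record: '%s'", path), call. = FALSE)
  v <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    mat5_read(path)
  }
  needed <- c("wavenumber_axis", "laser_wavelength_nm", "poly_coeffs",
              "calibration_datetime", "selected_peak_indices")
  missing <- setdiff(needed, names(v))
  if (length(missing) > 0L)
    stop(sprintf("calibration record '%s' is missing field(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  fit_rms <- if (length(v$fit_rms) == 1L && is.numeric(v$fit_rms))
    as.numeric(v$fit_rms) else NA_real_
  rec <- calibration_record(v$poly_coeffs, v$laser_wavelength_nm,
                            length(v$wavenumber_axis),
                            selected_peak_indices = v$selected_peak_indices,
                            calibration_datetime = v$calibration_datetime,
                            fit_rms = fit_rms)
  if (max(abs(rec$raman_shift_axis - v$wavenumber_axis)) > 1e-6)
    stop(sprintf("calibration record '%s' is inconsistent: stored axis does not match coefficients",
                 path), call. = FALSE)
  rec$raman_shift_axis <- as.numeric(v$wavenumber_axis)
  rec
}
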