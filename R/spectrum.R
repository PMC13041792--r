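AXIS_KINDS <- c("pixel", "absolute_wavenumber", "raman_shift", "wavelength")

#' Construct a Raman spectrum
#'
#' The central container every processing stage transforms: an ordered axis
#' paired with detector intensities. The axis may be a pixel index (raw
#' detector frames), an absolute wavenumber or Raman shift in cm-1, or a
#' wavelength in nm.
#'
#' @param axis Numeric vector, strictly increasing. Pixel axes are 0-based.
#' @param intensity Numeric vector of detector counts, same length as `axis`.
#' @param axis_kind One of `"pixel"`, `"absolute_wavenumber"`,
#'   `"raman_shift"`, `"wavelength"`.
#' @return An object of class `raman_spectrum`: a list with elements
#'   `axis`, `intensity`, `axis_kind`.
#' @examples
#' s <- raman_spectrum(c(900, 901.5, 903), c(10, 12, 11), "raman_shift")
#' s
#' @export
raman_spectrum <- function(axis, intensity, axis_kind = "raman_shift") {
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  axis_kind <- match.arg(axis_kind, AXIS_KINDS)
  if (length(axis) != length(intensity))
    stop("axis and intensity must have equal length", call. = FALSE)
  if (length(axis) < 2L)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (anyNA(axis) || any(!is.finite(axis)))
    stop("axis values must be finite", call. = FALSE)
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("intensities must be finite", call. = FALSE)
  if (is.unsorted(axis, strictly = TRUE)) {
    if (anyDuplicated(axis))
      stop("axis contains duplicate values", call. = FALSE)
    stop("axis must be strictly increasing", call. = FALSE)
  }
  structure(list(axis = axis, intensity = intensity, axis_kind = axis_kind),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, axis_kind=%s, axis [%g, %g]\n",
              length(x$axis), x$axis_kind, x$axis[1], x$axis[length(x$axis)]))
  invisible(x)
}

#' @export
as.data.frame.raman_spectrum <- function(x, ...) {
  data.frame(axis = x$axis, intensity = x$intensity)
}

#' @export
length.raman_spectrum <- function(x) length(x$axis)

is_spectrum <- function(x) inherits(x, "raman_spectrum")

stopifnot_spectrum <- function(s) {
  if (!is_spectrum(s)) stop("expected a raman_spectrum object", call. = FALSE)
  invisible(s)
}

## replace the intensity (same axis) without re-running full validation
with_intensity <- function(s, intensity) {
  if (any(!is.finite(intensity)))
    stop("operation produced non-finite intensities", call. = FALSE)
  s$intensity <- as.numeric(intensity)
  s
}

#' Canonical content hash of a spectrum
#'
#' SHA-256 over a canonical text serialization (axis kind plus every value
#' printed with 17 significant digits, the shortest representation that
#' round-trips an IEEE double). Used by the provenance log so that replay
#' checks are platform-stable.
#'
#' @param s A `raman_spectrum`.
#' @return A hex digest string.
#' @export
spectrum_hash <- function(s) {
  stopifnot_spectrum(s)
  digest::digest(paste(c(s$axis_kind, fmt_num(s$axis), fmt_num(s$intensity)),
                       collapse = "\n"), algo = "sha256", serialize = FALSE)
}

#' Assign a calibrated Raman-shift axis to a pixel-indexed spectrum
#'
#' Replaces the 0-based pixel axis with the per-pixel Raman-shift axis of a
#' calibration record. Because absolute wavenumber usually increases with
#' pixel index, the Raman shift decreases with pixel; the axis/intensity
#' pairing is reversed where needed so the result is ascending.
#'
#' @param s A pixel-indexed `raman_spectrum` whose length equals the detector
#'   pixel count of `record`.
#' @param record A [calibration_record()].
#' @return A `raman_spectrum` with `axis_kind = "raman_shift"`.
#' @export
apply_calibration <- function(s, record) {
  stopifnot_spectrum(s)
  if (s$axis_kind != "pixel")
    stop("apply_calibration expects a pixel-indexed spectrum", call. = FALSE)
  if (!inherits(record, "calibration_record"))
    stop("record must be a calibration_record", call. = FALSE)
  shift <- record$raman_shift_axis
  if (length(shift) != length(s$axis))
    stop(sprintf("calibration covers %d pixels but spectrum has %d points",
                 length(shift), length(s$axis)), call. = FALSE)
  ord <- order(shift)
  raman_spectrum(shift[ord], s$intensity[ord], "raman_shift")
}
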