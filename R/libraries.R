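#' Bundled neon-argon emission line library
#'
#' 52 Ne/Ar near-infrared emission lines in absolute wavenumber (cm-1),
#' spanning 9,677.994 to 12,947.060 cm-1 -- the standard atomic-line ladder
#' for pixel-to-wavenumber calibration of 785 nm dispersive Raman systems.
#' Interior entries are curated from published NIST Ne/Ar line lists
#' (converted from air wavelengths); the endpoints are fixed by the
#' library's documented span.
#'
#' @return A `reference_line_library`: list with `lines` (ascending cm-1),
#'   `species` (per-line element label) and `source_label`.
#' @export
ne_ar_library <- function() {
  path <- system.file("extdata", "ne_ar_lines.tsv", package = "ramanprep",
                      mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("wavenumber_cm1", "species"))
  lib <- structure(list(lines = df$wavenumber_cm1,
                        species = as.character(df$species),
                        source_label = "Ne-Ar NIR emission, v1.0"),
                   class = "reference_line_library")
  validate_line_library(lib)
  lib
}

validate_line_library <- function(lib) {
  if (is.unsorted(lib$lines, strictly = TRUE))
    stop("reference library lines must be strictly increasing", call. = FALSE)
  invisible(lib)
}

#' Bundled acetaminophen Raman-shift reference library
#'
#' 22 certified acetaminophen Raman shifts (cm-1) spanning 213.3 to
#' 3326.6 cm-1, curated from the ASTM E1840-style certified band list.
#' Used to estimate the excitation laser wavelength from a measured
#' acetaminophen spectrum once the pixel-to-wavenumber map is known.
#'
#' @return A `raman_reference_library`: list with `shifts` (ascending cm-1)
#'   and `analyte_label`.
#' @export
acetaminophen_library <- function() {
  path <- system.file("extdata", "acetaminophen_shifts.tsv",
                      package = "ramanprep", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("shift_cm1", "analyte"))
  lib <- structure(list(shifts = df$shift_cm1,
                        analyte_label = "acetaminophen, v1.0"),
                   class = "raman_reference_library")
  if (is.unsorted(lib$shifts, strictly = TRUE))
    stop("reference shifts must be strictly increasing", call. = FALSE)
  lib
}
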