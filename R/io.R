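#' Describe the on-disk layout of a delimited spectrum file
#'
#' Vendor export formats differ in delimiter, column layout and header
#' length; a dialect makes the expectation explicit instead of guessing
#' silently. With `delimiter = "auto"` the reader tries tab, then comma,
#' then whitespace, and keeps the first that parses.
#'
#' @param delimiter `"tab"`, `"comma"`, `"whitespace"` or `"auto"`.
#' @param columns `"axis_then_intensity"` (two columns) or
#'   `"intensity_only"` (single column; a 0-based pixel axis is synthesized).
#' @param header_rows Number of leading rows to skip.
#' @return A `spectrum_dialect` object.
#' @export
spectrum_dialect <- function(delimiter = "auto",
                             columns = "axis_then_intensity",
                             header_rows = 0L) {
  delimiter <- match.arg(delimiter, c("auto", "tab", "comma", "whitespace"))
  columns <- match.arg(columns, c("axis_then_intensity", "intensity_only"))
  header_rows <- as.integer(header_rows)
  if (is.na(header_rows) || header_rows < 0L)
    stop("header_rows must be a non-negative integer", call. = FALSE)
  structure(list(delimiter = delimiter, columns = columns,
                 header_rows = header_rows), class = "spectrum_dialect")
}

delim_regex <- function(delimiter) {
  switch(delimiter, tab = "\t", comma = ",", whitespace = "[[:space:]]+")
}

## parse non-header lines under one concrete delimiter; returns a numeric
## matrix or a condition describing the first offending row
parse_rows <- function(lines, delimiter, ncol_expected) {
  rx <- delim_regex(delimiter)
  parts <- strsplit(trimws(lines), rx)
  n_fields <- lengths(parts)
  if (any(n_fields != ncol_expected))
    return(simpleError(sprintf(
      "row %d has %d field(s), expected %d (delimiter=%s)",
      which(n_fields != ncol_expected)[1], n_fields[n_fields != ncol_expected][1],
      ncol_expected, delimiter)))
  vals <- suppressWarnings(vapply(parts, as.numeric, numeric(ncol_expected)))
  vals <- matrix(vals, ncol = ncol_expected, byrow = TRUE)
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    return(simpleError(sprintf("non-numeric value in row %d: '%s'",
                               bad, lines[bad])))
  }
  vals
}

#' Read a spectrum from a delimited text file
#'
#' Accepts two-column (axis, intensity) or single-column (intensity only)
#' files. Files with a descending axis are accepted and sorted ascending,
#' reordering intensities in lockstep; duplicate axis values are rejected
#' because they make downstream interpolation ambiguous.
#'
#' @param path File path.
#' @param dialect A [spectrum_dialect()].
#' @param axis_kind Axis unit of two-column files; single-column files are
#'   always `"pixel"` with a 0-based integer axis.
#' @return A [raman_spectrum()].
#' @export
read_spectrum <- function(path, dialect = spectrum_dialect(),
                          axis_kind = "raman_shift") {
  if (!inherits(dialect, "spectrum_dialect"))
    stop("dialect must be a spectrum_dialect", call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("cannot read spectrum: no such file '%s'", path), call. = FALSE)
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop(sprintf(
                      "I/O error reading '%s': %s", path, conditionMessage(e)),
                      call. = FALSE))
  if (dialect$header_rows > 0L) {
    if (length(lines) <= dialect$header_rows)
      stop(sprintf("'%s': fewer rows than header_rows=%d", path,
                   dialect$header_rows), call. = FALSE)
    lines <- lines[-seq_len(dialect$header_rows)]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop(sprintf("'%s': a spectrum file needs at least 2 data rows", path),
         call. = FALSE)
  ncol_expected <- if (dialect$columns == "intensity_only") 1L else 2L
  tries <- if (dialect$delimiter == "auto") c("tab", "comma", "whitespace")
           else dialect$delimiter
  vals <- NULL
  errs <- character(0)
  for (d in tries) {
    out <- parse_rows(lines, d, ncol_expected)
    if (!inherits(out, "error")) { vals <- out; break }
    errs <- c(errs, conditionMessage(out))
  }
  if (is.null(vals))
    stop(sprintf("'%s': could not parse: %s", path, errs[length(errs)]),
         call. = FALSE)
  if (dialect$columns == "intensity_only") {
    axis <- seq_len(nrow(vals)) - 1
    intensity <- vals[, 1]
    axis_kind <- "pixel"
  } else {
    axis <- vals[, 1]
    intensity <- vals[, 2]
  }
  ord <- order(axis)
  axis <- axis[ord]
  intensity <- intensity[ord]
  if (anyDuplicated(axis))
    stop(sprintf("'%s': duplicate axis value %s", path,
                 fmt_num(axis[duplicated(axis)][1])), call. = FALSE)
  raman_spectrum(axis, intensity, axis_kind)
}

#' Write a processed spectrum as two-column tab-delimited text
#'
#' The final pipeline product: Raman-shift axis and normalized intensity,
#' printed with 17 significant digits so that re-reading the file
#' reproduces every double bit-for-bit.
#'
#' @param path Output path.
#' @param spectrum A `raman_spectrum` with `axis_kind = "raman_shift"`.
#' @export
write_processed_spectrum <- function(path, spectrum) {
  stopifnot_spectrum(spectrum)
  if (spectrum$axis_kind != "raman_shift")
    stop("processed outputs must be on a Raman-shift axis", call. = FALSE)
  lines <- paste(fmt_num(spectrum$axis), fmt_num(spectrum$intensity), sep = "\t")
  tryCatch(writeLines(lines, path),
           error = function(e) stop(sprintf("I/O error writing '%s': %s",
                                            path, conditionMessage(e)),
                                    call. = FALSE))
  invisible(path)
}

#' Construct a spectral response correction factor
#'
#' A multiplicative curve C on its own axis; applying the correction
#' multiplies a spectrum's intensities by C resampled onto its axis.
#'
#' @param axis Strictly increasing axis values.
#' @param factor Strictly positive correction values, same length.
#' @param axis_unit `"raman_shift"` (cm-1) or `"wavelength"` (nm).
#' @return A `correction_factor` object.
#' @export
correction_factor <- function(axis, factor, axis_unit = "raman_shift") {
  axis <- as.numeric(axis)
  factor <- as.numeric(factor)
  axis_unit <- match.arg(axis_unit, c("raman_shift", "wavelength"))
  if (length(axis) != length(factor))
    stop("axis and factor must have equal length", call. = FALSE)
  if (length(axis) < 2L)
    stop("a correction factor needs at least 2 points", call. = FALSE)
  if (is.unsorted(axis, strictly = TRUE))
    stop("correction factor axis must be strictly increasing", call. = FALSE)
  if (any(!is.finite(factor)) || any(factor <= 0))
    stop("correction factor values must be finite and strictly positive",
         call. = FALSE)
  structure(list(axis = axis, factor = factor, axis_unit = axis_unit),
            class = "correction_factor")
}

#' @export
print.correction_factor <- function(x, ...) {
  cat(sprintf("<correction_factor> %d points on %s axis [%g, %g]\n",
              length(x$axis), x$axis_unit, x$axis[1], x$axis[length(x$axis)]))
  invisible(x)
}

#' Read a correction factor from text, CSV or spreadsheet
#'
#' Two columns (axis, factor). `.xlsx`/`.xls` files are read with readxl;
#' anything else is treated as delimited text with automatic delimiter
#' detection. Non-positive factor values are rejected.
#'
#' @param path File path.
#' @param axis_unit Axis unit of the stored curve.
#' @return A [correction_factor()].
#' @export
read_correction_factor <- function(path, axis_unit = "raman_shift") {
  if (!file.exists(path))
    stop(sprintf("cannot read correction factor: no such file '%s'", path),
         call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    df <- readxl::read_excel(path, col_names = FALSE,
                             col_types = c("numeric", "numeric"),
                             .name_repair = "minimal")
    axis <- as.numeric(df[[1]])
    fac <- as.numeric(df[[2]])
    if (anyNA(axis) || anyNA(fac))
      stop(sprintf("'%s': non-numeric cell in spreadsheet", path), call. = FALSE)
  } else {
    s <- read_spectrum(path, spectrum_dialect("auto", "axis_then_intensity", 0L))
    axis <- s$axis
    fac <- s$intensity
  }
  ord <- order(axis)
  correction_factor(axis[ord], fac[ord], axis_unit)
}

#' Write a correction factor as two-column tab-delimited text
#'
#' @param path Output path (conventionally `WL_CORR.txt` for the white-light
#'   pathway).
#' @param cf A [correction_factor()].
#' @export
write_correction_factor <- function(path, cf) {
  if (!inherits(cf, "correction_factor"))
    stop("cf must be a correction_factor", call. = FALSE)
  writeLines(paste(fmt_num(cf$axis), fmt_num(cf$factor), sep = "\t"), path)
  invisible(path)
}
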