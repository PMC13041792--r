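## shared by the single-spectrum path, the preview and the batch engine:
## read -> (calibrate) -> run the P1-P8 pipeline
process_one <- function(input, sys_cfg, pipe_cfg, cal = NULL, cf = NULL,
                        dialect = spectrum_dialect()) {
  path <- resolve_execution_path(sys_cfg, pipe_cfg)
  s <- if (is_spectrum(input)) input else read_spectrum(input, dialect)
  if (path$run_calibration && s$axis_kind == "pixel") {
    if (is.null(cal))
      stop("configuration error: the system requires calibration but no calibration record was supplied",
         call. = FALSE)
    s <- apply_calibration(s, cal)
  }
  if (s$axis_kind != "raman_shift")
    stop(sprintf("input axis kind '%s' cannot enter the pipeline; a Raman-shift axis is required",
                 s$axis_kind), call. = FALSE)
  apply_src <- path$run_src && pipe_cfg$apply_src
  if (apply_src && is.null(cf))
    stop("configuration error: the system requires spectral response correction but no correction factor was supplied",
         call. = FALSE)
  res <- run_pipeline(s, pipe_cfg, cf, apply_src = apply_src)
  res$provenance$system_config <- sys_cfg
  res$input <- s
  res
}

## output filename with the key parameters and a timestamp embedded:
## <stem>__s<start>_e<stop>_b<width>_n<norm>__<timestamp>.txt
batch_output_name <- function(input_path, pipe_cfg, stamp) {
  stem <- tools::file_path_sans_ext(basename(input_path))
  sprintf("%s__s%s_e%s_b%s_n%s__%s.txt", stem,
          fmt_compact(pipe_cfg$truncate_start),
          fmt_compact(pipe_cfg$truncate_stop),
          fmt_compact(pipe_cfg$bin_width),
          pipe_cfg$normalization, stamp)
}

#' Process a batch of spectrum files
#'
#' Runs every input through the identical single-spectrum implementation.
#' Each file is processed independently: a failure is captured in the
#' report with its error text and does not abort the batch. Outputs are
#' written as two-column text with the key processing parameters and a
#' timestamp embedded in the filename, each with a JSON provenance sidecar.
#'
#' @param inputs Character vector of spectrum file paths.
#' @param sys_cfg A [system_config()].
#' @param pipe_cfg A [pipeline_config()].
#' @param cal A [calibration_record()] or `NULL`.
#' @param cf A [correction_factor()] or `NULL`.
#' @param out_dir Writable output directory (created if absent).
#' @param dialect [spectrum_dialect()] of the input files.
#' @return A `batch_report`: `list(n_success, n_fail, files)` where `files`
#'   is a data frame with columns `input`, `status`, `output`, `error`.
#' @export
run_batch <- function(inputs, sys_cfg, pipe_cfg, cal = NULL, cf = NULL,
                      out_dir, dialect = spectrum_dialect()) {
  if (length(inputs) == 0L)
    stop("run_batch needs at least one input file", call. = FALSE)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stamp <- file_timestamp()
  rows <- lapply(inputs, function(f) {
    out_name <- batch_output_name(f, pipe_cfg, stamp)
    res <- tryCatch(
      process_one(f, sys_cfg, pipe_cfg, cal, cf, dialect),
      error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(input = f, status = "failed", output = NA_character_,
                        error = conditionMessage(res)))
    out_path <- file.path(out_dir, out_name)
    write_processed_spectrum(out_path, res$spectrum)
    record_provenance(res$provenance,
                      paste0(out_path, ".provenance.json"))
    data.frame(input = f, status = "success", output = out_name,
               error = NA_character_)
  })
  files <- do.call(rbind, rows)
  structure(list(n_success = sum(files$status == "success"),
                 n_fail = sum(files$status == "failed"),
                 files = files, out_dir = out_dir, timestamp = stamp),
            class = "batch_report")
}

#' @export
print.batch_report <- function(x, ...) {
  cat(sprintf("<batch_report> %d success(es), %d failure(s)\n",
              x$n_success, x$n_fail))
  failed <- x$files[x$files$status == "failed", , drop = FALSE]
  for (i in seq_len(nrow(failed)))
    cat(sprintf("  FAILED %s: %s\n", failed$input[i], failed$error[i]))
  invisible(x)
}

#' Preview the first file of a batch
#'
#' Validates a batch setup by processing only the first input through the
#' same implementation the batch engine uses. Nothing is written to disk.
#'
#' @inheritParams run_batch
#' @return `list(spectrum, provenance)` for the first input.
#' @export
preview_first <- function(inputs, sys_cfg, pipe_cfg, cal = NULL, cf = NULL,
                          dialect = spectrum_dialect()) {
  if (length(inputs) == 0L)
    stop("preview_first needs at least one input file", call. = FALSE)
  res <- process_one(inputs[[1L]], sys_cfg, pipe_cfg, cal, cf, dialect)
  list(spectrum = res$spectrum, provenance = res$provenance)
}

#' Process a single spectrum end to end
#'
#' The interactive-equivalent path: identical implementation to each batch
#' entry (the batch/single hash-equality guarantee rests on this sharing).
#'
#' @inheritParams run_batch
#' @param input A spectrum file path or a `raman_spectrum`.
#' @return `list(spectrum, provenance)`.
#' @export
process_spectrum <- function(input, sys_cfg, pipe_cfg, cal = NULL, cf = NULL,
                             dialect = spectrum_dialect()) {
  res <- process_one(input, sys_cfg, pipe_cfg, cal, cf, dialect)
  list(spectrum = res$spectrum, provenance = res$provenance)
}
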