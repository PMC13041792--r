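#' Provenance log of a pipeline run
#'
#' An ordered record of every stage that touched a spectrum -- applied,
#' skipped and no-op alike -- with the parameters used, content hashes of
#' each stage's input and output, and verbatim snapshots of the governing
#' configurations. The embedded snapshots make a log self-contained:
#' [replay_provenance()] re-executes the run from the log alone and checks
#' the recorded output hash.
#'
#' @param entries List of per-stage records (`stage`, `operation`,
#'   `parameters`, `status`, `input_hash`, `output_hash`, `timestamp`).
#' @param pipeline_config The [pipeline_config()] that governed the run.
#' @param system_config Optional [system_config()] snapshot.
#' @param correction_factor The [correction_factor()] applied at P2, or
#'   `NULL`.
#' @param input_hash,output_hash Content hashes of the run's overall input
#'   and output spectra.
#' @return A `provenance_log` object.
#' @export
provenance_log <- function(entries, pipeline_config, system_config = NULL,
                           correction_factor = NULL, input_hash, output_hash) {
  stages <- vapply(entries, `[[`, character(1), "stage")
  if (is.unsorted(match(stages, PIPELINE_STAGES), strictly = TRUE))
    stop("provenance entries must appear in strictly increasing stage order",
         call. = FALSE)
  structure(list(entries = entries,
                 pipeline_config = pipeline_config,
                 system_config = system_config,
                 correction_factor = correction_factor,
                 input_hash = input_hash, output_hash = output_hash),
            class = "provenance_log")
}

#' @export
print.provenance_log <- function(x, ...) {
  cat(sprintf("<provenance_log> %d entries, input %s.., output %s..\n",
              length(x$entries), substr(x$input_hash, 1, 8),
              substr(x$output_hash, 1, 8)))
  for (e in x$entries)
    cat(sprintf("  %s %-22s %s\n", e$stage, e$operation, e$status))
  invisible(x)
}

## strip nulls so jsonlite round trips cleanly
drop_null <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, drop_null)
}

#' Serialize a provenance log as JSON
#'
#' @param log A [provenance_log()].
#' @param path Output path (conventionally the processed-output name plus
#'   `.provenance.json`).
#' @export
record_provenance <- function(log, path) {
  if (!inherits(log, "provenance_log"))
    stop("log must be a provenance_log", call. = FALSE)
  payload <- list(
    entries = lapply(log$entries, drop_null),
    pipeline_config = unclass(log$pipeline_config),
    system_config = if (!is.null(log$system_config))
      unclass(log$system_config),
    correction_factor = if (!is.null(log$correction_factor))
      list(axis = log$correction_factor$axis,
           factor = log$correction_factor$factor,
           axis_unit = log$correction_factor$axis_unit),
    input_hash = log$input_hash, output_hash = log$output_hash)
  jsonlite::write_json(drop_null(payload), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a provenance log written by [record_provenance()]
#'
#' @param path JSON file path.
#' @return A `provenance_log`.
#' @export
read_provenance <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cfg <- do.call(pipeline_config, v$pipeline_config)
  sys_cfg <- if (!is.null(v$system_config))
    do.call(system_config, v$system_config)
  cf <- if (!is.null(v$correction_factor))
    correction_factor(unlist(v$correction_factor$axis),
                      unlist(v$correction_factor$factor),
                      v$correction_factor$axis_unit)
  entries <- lapply(v$entries, function(e) {
    e$parameters <- as.list(e$parameters)
    e
  })
  provenance_log(entries, cfg, system_config = sys_cfg,
                 correction_factor = cf,
                 input_hash = v$input_hash, output_hash = v$output_hash)
}

#' Replay a recorded run and verify its output hash
#'
#' Re-executes the pipeline on `input` using only the configuration and
#' correction factor embedded in the log, then compares input and output
#' content hashes against the recorded ones. This is the operational form
#' of the determinism guarantee: identical input under identical
#' configuration must reproduce the identical output.
#'
#' @param log A [provenance_log()] (or a path to one).
#' @param input The original input `raman_spectrum`.
#' @return `TRUE` invisibly on success; error otherwise.
#' @export
replay_provenance <- function(log, input) {
  if (is.character(log)) log <- read_provenance(log)
  if (!inherits(log, "provenance_log"))
    stop("log must be a provenance_log or a path to one", call. = FALSE)
  stopifnot_spectrum(input)
  if (spectrum_hash(input) != log$input_hash)
    stop("replay error: input spectrum does not match the recorded input hash",
         call. = FALSE)
  p2 <- log$entries[[2L]]
  res <- run_pipeline(input, log$pipeline_config, log$correction_factor,
                      apply_src = identical(p2$status, "applied"))
  if (spectrum_hash(res$spectrum) != log$output_hash)
    stop("replay error: recomputed output hash differs from the recorded one",
         call. = FALSE)
  invisible(TRUE)
}
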