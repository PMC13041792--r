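test_that("execution paths mirror the instrument's requirements", {
  pipe <- pipeline_config()
  ren <- resolve_execution_path(system_config("Renishaw"), pipe)
  expect_false(ren$run_calibration)
  expect_false(ren$run_src)
  expect_false(ren$stages$active[ren$stages$stage == "P2"])

  cart <- resolve_execution_path(system_config("Cart"), pipe)
  expect_true(cart$run_calibration)
  expect_true(cart$run_src)
  expect_true(cart$stages$active[cart$stages$stage == "P2"])

  # custom with both flags false is path-identical to Renishaw
  cust <- resolve_execution_path(
    system_config("custom", requires_calibration = FALSE,
                  requires_src = FALSE), pipe)
  expect_identical(cust$stages, ren$stages)
  expect_identical(cust$run_src, ren$run_src)

  # pipeline-level opt-out also deactivates P2
  cart2 <- resolve_execution_path(system_config("Cart"),
                                  pipeline_config(apply_src = FALSE))
  expect_false(cart2$stages$active[2])
  # stage sequence itself is immutable
  expect_identical(cart$stages$stage, pipeline_stages())
})

test_that("config files round-trip and the schema is strict", {
  td <- withr::local_tempdir()
  sys_cfg <- system_config("Portable", 830, detector = "CCD-A",
                           spectral_range = c(200, 3200))
  sp <- file.path(td, "config.json")
  save_system_config(sp, sys_cfg)
  expect_equal(load_system_config(sp), sys_cfg)

  pipe <- pipeline_config(bin_width = 2, normalization = "area",
                          smoothing = list(method = "savgol", window = 9,
                                           polyorder = 3))
  pp <- file.path(td, "preprocessing.json")
  save_pipeline_config(pp, pipe)
  expect_equal(load_pipeline_config(pp), pipe)

  # misspelled key is rejected by name
  writeLines('{"truncate_start": 900, "binwdith": 3.5}', pp)
  expect_error(load_pipeline_config(pp), "binwdith")
  writeLines('{"system": "Cart", "excitation_wavelength_nm": 785, "lazer": 1}',
             sp)
  expect_error(load_system_config(sp), "lazer")
  writeLines('{"detector": "X"}', sp)
  expect_error(load_system_config(sp), "missing required")
  # attempting to reorder the pipeline through configuration is an error
  writeLines('{"stage_order": ["P4", "P1"]}', pp)
  expect_error(load_pipeline_config(pp), "stage_order")

  # an empty pipeline file yields the documented defaults
  writeLines("{}", pp)
  defaults <- load_pipeline_config(pp)
  expect_equal(defaults$truncate_start, 900)
  expect_equal(defaults$truncate_stop, 1700)
  expect_equal(defaults$bin_width, 3.5)
  expect_identical(defaults$smoothing$method, "none")
})

test_that("batch processing isolates per-file failures and names them", {
  td <- withr::local_tempdir()
  inputs <- write_sample_files(file.path(td, "in"), n = 3, seed0 = 300)
  corrupt <- file.path(td, "in", "corrupt.txt")
  writeLines(c("900\tten", "901\televen"), corrupt)
  report <- run_batch(c(inputs, corrupt), uncalibrated_system(),
                      pipeline_config(), out_dir = file.path(td, "out"))
  expect_equal(report$n_success, 3L)
  expect_equal(report$n_fail, 1L)
  expect_equal(report$n_success + report$n_fail, 4L)
  failed <- report$files[report$files$status == "failed", ]
  expect_match(failed$input, "corrupt.txt")
  expect_match(failed$error, "row 1")
  # outputs exist for the successes, with provenance sidecars
  outs <- list.files(file.path(td, "out"))
  expect_length(grep("provenance", outs, invert = TRUE, value = TRUE), 3L)
  expect_length(grep("provenance", outs, value = TRUE), 3L)
})

test_that("output filenames embed the processing parameters and timestamp", {
  td <- withr::local_tempdir()
  inputs <- write_sample_files(file.path(td, "in"), n = 1, seed0 = 310)
  cfg <- pipeline_config(truncate_start = 905, truncate_stop = 1695,
                         bin_width = 4.5, normalization = "max")
  report <- run_batch(inputs, uncalibrated_system(), cfg,
                      out_dir = file.path(td, "out"))
  out <- report$files$output[1]
  expect_match(out, "^sample_01__s905_e1695_b4\\.5_nmax__[0-9]{8}T[0-9]{6}\\.txt$")
})

test_that("batch, preview and single-spectrum paths agree hash-for-hash", {
  td <- withr::local_tempdir()
  inputs <- write_sample_files(file.path(td, "in"), n = 3, seed0 = 320)
  sys_cfg <- uncalibrated_system()
  cfg <- pipeline_config()
  report <- run_batch(inputs, sys_cfg, cfg, out_dir = file.path(td, "out"))
  expect_equal(report$n_success, 3L)
  for (i in seq_along(inputs)) {
    single <- process_spectrum(inputs[i], sys_cfg, cfg)
    batch_out <- read_spectrum(file.path(td, "out",
                                         report$files$output[i]))
    expect_identical(spectrum_hash(single$spectrum), spectrum_hash(batch_out))
  }
  # preview equals the batch entry for the first file and writes nothing
  before <- list.files(file.path(td, "out"))
  prev <- preview_first(inputs, sys_cfg, cfg)
  expect_identical(list.files(file.path(td, "out")), before)
  expect_identical(spectrum_hash(prev$spectrum),
                   spectrum_hash(read_spectrum(
                     file.path(td, "out", report$files$output[1]))))
  expect_error(preview_first(character(0), sys_cfg, cfg), "at least one")
})

test_that("identical configuration in different working directories reproduces outputs", {
  base <- withr::local_tempdir()
  inputs <- write_sample_files(file.path(base, "in"), n = 2, seed0 = 330)
  cfgp <- file.path(base, "preprocessing.json")
  sysp <- file.path(base, "config.json")
  save_pipeline_config(cfgp, pipeline_config(
    smoothing = list(method = "savgol", window = 7, polyorder = 2)))
  save_system_config(sysp, uncalibrated_system())
  hashes <- lapply(c("runA", "runB"), function(run) {
    wd <- file.path(base, run)
    dir.create(wd)
    withr::with_dir(wd, {
      rep <- run_batch(inputs, load_system_config(sysp),
                       load_pipeline_config(cfgp), out_dir = "out")
      vapply(file.path("out", rep$files$output), function(f)
        spectrum_hash(read_spectrum(f)), character(1), USE.NAMES = FALSE)
    })
  })
  expect_identical(hashes[[1]], hashes[[2]])
})

test_that("bypass soundness: unused calibration/correction inputs change nothing", {
  td <- withr::local_tempdir()
  inputs <- write_sample_files(file.path(td, "in"), n = 1, seed0 = 340)
  sys_cfg <- system_config("Renishaw")  # requires neither stage
  cfg <- pipeline_config()
  cal <- calibration_record(c(9300, 3.2, -1e-4, 1e-8), 785.142, 1340)
  cf <- correction_factor(c(0, 4000), c(2, 2))
  bare <- process_spectrum(inputs[1], sys_cfg, cfg)
  loaded <- process_spectrum(inputs[1], sys_cfg, cfg, cal = cal, cf = cf)
  expect_identical(spectrum_hash(bare$spectrum), spectrum_hash(loaded$spectrum))
})

test_that("systems requiring inputs fail with configuration errors when they are absent", {
  td <- withr::local_tempdir()
  inputs <- write_sample_files(file.path(td, "in"), n = 1, seed0 = 350)
  # Cart requires SRC: missing factor is a configuration error at run time
  expect_error(process_spectrum(inputs[1], system_config("Cart"),
                                pipeline_config()),
               "no correction factor")
  # pixel-indexed input without a calibration record
  pxf <- file.path(td, "pixel.txt")
  writeLines(sprintf("%d", round(runif(1340) * 100)), pxf)
  expect_error(process_spectrum(pxf, system_config("Cart"), pipeline_config(),
                                cf = correction_factor(c(0, 4000), c(1, 1)),
                                dialect = spectrum_dialect("auto", "intensity_only")),
               "no calibration record")
})

test_that("calibrated pixel inputs flow through the batch engine", {
  td <- withr::local_tempdir()
  m <- sample_model(seed = 77)
  samp <- gen_sample_spectrum(m)
  # write the same data as a pixel-indexed, detector-ordered file
  rec <- calibration_record(m$true_coeffs, m$laser_wavelength_nm, m$n_pixels)
  ord <- order(rec$raman_shift_axis)
  counts <- numeric(m$n_pixels)
  counts[ord] <- samp$spectrum$intensity
  pxf <- file.path(td, "frame.txt")
  writeLines(sprintf("%.17g", counts), pxf)
  res <- process_spectrum(pxf, system_config("Cart", requires_src = FALSE),
                          pipeline_config(), cal = rec,
                          dialect = spectrum_dialect("auto", "intensity_only"))
  direct <- run_pipeline(samp$spectrum, pipeline_config(), apply_src = FALSE)
  expect_equal(res$spectrum$intensity, direct$spectrum$intensity)
})

test_that("provenance logs are complete, self-contained and replayable", {
  td <- withr::local_tempdir()
  m <- sample_model(seed = 88)
  s <- gen_sample_spectrum(m)$spectrum
  cf <- correction_factor(c(-1000, 4000), c(1.25, 1.25))
  sys_cfg <- system_config("Cart", requires_calibration = FALSE)
  cfg <- pipeline_config(smoothing = list(method = "median", window = 5))
  res <- process_spectrum(s, sys_cfg, cfg, cf = cf)

  # one entry per stage, skipped ones included
  stages <- vapply(res$provenance$entries, `[[`, character(1), "stage")
  expect_identical(stages, pipeline_stages())

  # serialized log replays from its embedded config + factor alone
  logp <- file.path(td, "run.provenance.json")
  record_provenance(res$provenance, logp)
  expect_true(replay_provenance(logp, s))
  expect_error(replay_provenance(logp, p1_baseline_subtract(s)),
               "input spectrum does not match")

  # embedded snapshots byte-equal freshly serialized configs
  v <- jsonlite::read_json(logp, simplifyVector = TRUE)
  ref <- file.path(td, "ref.json")
  save_pipeline_config(ref, cfg)
  expect_identical(jsonlite::read_json(ref, simplifyVector = TRUE),
                   v$pipeline_config)
})
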