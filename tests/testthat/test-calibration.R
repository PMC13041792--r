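test_that("bundled reference libraries load with valid structure", {
  lib <- ne_ar_library()
  expect_true(!is.unsorted(lib$lines, strictly = TRUE))
  expect_length(lib$species, length(lib$lines))
  acet <- acetaminophen_library()
  expect_true(!is.unsorted(acet$shifts, strictly = TRUE))
})

test_that("refine_peak finds the centroid of the local peak span", {
  # symmetric triangular peak at pixel 100 on a flat background: the
  # centroid must sit at the apex
  p <- 0:200
  I <- pmax(0, 10 - abs(p - 100))
  s <- raman_spectrum(p, I, "pixel")
  expect_lt(abs(refine_peak(s, 98) - 100), 0.25)

  # two-peak spectrum: refinement near the first apex must use only the
  # first span; oracle = brute-force centroid over the exhaustive
  # sign-change span of the smoothed derivative
  I2 <- 5 + 80 * exp(-0.5 * ((p - 60) / 3)^2) + 120 * exp(-0.5 * ((p - 90) / 3)^2)
  s2 <- raman_spectrum(p, I2, "pixel")
  got <- refine_peak(s2, 58)
  # documented span rule, scanned explicitly: apex = +/- derivative crossing
  # nearest the pick, span bounded by flanking sign changes within the
  # 15-px search window
  d <- signal::sgolayfilt(I2, p = 2, n = 7, m = 1)
  i0 <- which.min(abs(p - 58))
  lo <- i0 - 15L; hi <- i0 + 15L
  cand <- lo:(hi - 1L)
  cand <- cand[d[cand] > 0 & d[cand + 1L] <= 0]
  apex <- cand[which.min(abs(cand - i0))]
  span_lo <- apex; while (span_lo > lo && d[span_lo - 1L] > 0) span_lo <- span_lo - 1L
  span_hi <- apex + 1L; while (span_hi < hi && d[span_hi + 1L] < 0) span_hi <- span_hi + 1L
  oracle <- sum(p[span_lo:span_hi] * I2[span_lo:span_hi]) /
    sum(I2[span_lo:span_hi])
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_lt(abs(got - 60), 1.5)   # stays on the first peak

  # sub-pixel Gaussian: centroid within 0.3 px of the dense-grid truth
  p3 <- 0:511
  s3 <- raman_spectrum(p3, 1000 * exp(-0.5 * ((p3 - 412.3) / 2.5)^2), "pixel")
  expect_lt(abs(refine_peak(s3, 412) - 412.3), 0.3)
})

test_that("refine_peak raises no-peak errors on flat or peakless input", {
  p <- 0:100
  expect_error(refine_peak(raman_spectrum(p, rep(3, 101), "pixel"), 50), "flat")
  # monotone ramp has no +/- derivative crossing
  expect_error(refine_peak(raman_spectrum(p, p * 1.0 + 1, "pixel"), 50),
               "no peak")
  s <- raman_spectrum(p, rnorm(101), "pixel")
  expect_error(refine_peak(s, 50, sg_window = 8), "odd")
  expect_error(refine_peak(s, 500), "range")
})

test_that("the cubic pixel-to-wavenumber fit recovers generating coefficients", {
  a <- c(9500, 3.2, -1e-4, 1e-8)
  px <- seq(100, 700, by = 100)
  pairs <- cbind(px, polyval_asc(a, px))
  fit <- fit_pixel_to_wavenumber(pairs)
  expect_lt(max(abs(fit - a) / abs(a)), 1e-8)
  expect_lt(attr(fit, "rms"), 1e-6)

  # exactly 4 points: interpolating cubic, zero residual
  fit4 <- fit_pixel_to_wavenumber(pairs[1:4, ])
  expect_lt(max(abs(attr(fit4, "residuals"))), 1e-7)

  # nested-model consistency: quadratic/cubic terms vanish for linear truth
  lin <- cbind(px, 9500 + 3.2 * px)
  fitl <- fit_pixel_to_wavenumber(lin)
  expect_lt(abs(fitl[3]), 1e-10 * abs(fitl[2]))
  expect_lt(abs(fitl[4]), 1e-10 * abs(fitl[2]))

  expect_error(fit_pixel_to_wavenumber(pairs[1:3, ]), "at least 4")
  degenerate <- cbind(c(1, 1, 1, 1, 2), c(10, 11, 12, 13, 14))
  expect_error(fit_pixel_to_wavenumber(degenerate), "singular|rank")
})

test_that("coefficient recovery holds across random monotone cubics", {
  set.seed(11)
  for (i in 1:10) {
    a <- c(runif(1, 9000, 10000), runif(1, 2, 4),
           runif(1, -2e-4, 0), runif(1, 0, 2e-8))
    px <- sort(runif(9, 0, 1339))
    fit <- fit_pixel_to_wavenumber(cbind(px, polyval_asc(a, px)))
    expect_lt(max(abs(fit - a) / pmax(abs(a), 1e-12)), 1e-6)
  }
})

test_that("evaluate_calibration is the ascending-power Horner evaluation", {
  expect_identical(evaluate_calibration(c(1, 0, 0, 0), 123), 1)
  expect_identical(evaluate_calibration(c(0, 1, 0, 0), 250), 250)
  # hand arithmetic: 9500 + 3.2*500 - 1e-4*500^2 + 1e-8*500^3
  expect_equal(evaluate_calibration(c(9500, 3.2, -1e-4, 1e-8), 500), 11076.25)
  expect_error(evaluate_calibration(c(1, 2, 3), 1), "length 4")
})

test_that("laser-wavelength estimation averages the per-peak inversions", {
  # constructed inverse: all denominators equal 1e7/785 -> exactly 785 nm
  a <- c(9300, 3.2, -1e-4, 1e-8)
  shifts <- c(500, 1000, 1500)
  target_abs <- 1e7 / 785 - shifts
  px <- vapply(target_abs, function(v)
    uniroot(function(p) polyval_asc(a, p) - v, c(0, 2000), tol = 1e-12)$root,
    numeric(1))
  est <- estimate_laser_wavelength(a, px, shifts)
  expect_equal(as.numeric(est), 785, tolerance = 1e-9)

  # two-peak mean and spread: per-peak estimates 785 and 787 -> 786, spread 2
  px2 <- vapply(c(1e7 / 785, 1e7 / 787) - 1000, function(v)
    uniroot(function(p) polyval_asc(a, p) - v, c(0, 2000), tol = 1e-12)$root,
    numeric(1))
  est2 <- estimate_laser_wavelength(a, px2, c(1000, 1000))
  expect_equal(as.numeric(est2), 786, tolerance = 1e-6)
  expect_equal(attr(est2, "spread"), 2, tolerance = 1e-6)

  expect_error(estimate_laser_wavelength(a, numeric(0), numeric(0)),
               "insufficient|no matched")
  expect_error(estimate_laser_wavelength(c(0, 1, 0, 0), 5, -100), "positive")
})

test_that("the Raman-shift axis is laser minus absolute wavenumber", {
  # spectrum at the laser line maps to zero shift
  lam <- 785
  expect_equal(compute_raman_shift_axis(c(1e7 / lam, 0, 0, 0), lam, 4),
               rep(0, 4))
  # hand arithmetic: 1e7/785 - 11738.8535 = 1000.0000 cm-1
  ax <- compute_raman_shift_axis(c(11738.8535, 0, 0, 0), 785, 2)
  expect_equal(ax[1], 1000, tolerance = 1e-3)
  # monotone increasing vabs gives monotone decreasing shift
  ax2 <- compute_raman_shift_axis(c(9300, 3.2, 0, 0), 785, 100)
  expect_true(all(diff(ax2) < 0))
  expect_error(compute_raman_shift_axis(c(1, 0, 0, 0), -5, 4), "positive")
})

test_that("shift axis and calibration evaluation are mutual inverses", {
  a <- c(9300, 3.2, -1e-4, 1e-8)
  lam <- 785.142
  ax <- compute_raman_shift_axis(a, lam, 256)
  vabs <- 1e7 / lam - ax
  expect_equal(vabs, evaluate_calibration(a, 0:255), tolerance = 1e-10)
  # and through the wavelength conversion used by response correction
  lam_scatter <- raman_shift_to_wavelength(ax[ax < 1e7 / lam], lam)
  back <- 1e7 / lam - 1e7 / lam_scatter
  expect_equal(back, ax[ax < 1e7 / lam], tolerance = 1e-9)
})

test_that("build_calibration_record recovers a noiseless synthetic truth end to end", {
  lib <- ne_ar_library()
  m <- forward_model(baseline_coeffs = 0, seed = 5)
  # seven lines spread across the detector
  sel <- c(1, 9, 17, 26, 34, 43, 52)
  lamp <- gen_lamp_spectrum(m, lib, sel)
  rec <- suppressWarnings(build_calibration_record(
    lamp$spectrum, lib, sel, round(lamp$truth_pixels),
    laser = list(mode = "direct", wavelength_nm = 785.142)))
  truth_axis <- compute_raman_shift_axis(m$true_coeffs, 785.142, m$n_pixels)
  expect_lt(max(abs(rec$raman_shift_axis - truth_axis)), 0.1)
  expect_identical(rec$selected_peak_indices, as.integer(sel))

  # determinism: rebuilding from the same inputs differs only in timestamp
  rec2 <- suppressWarnings(build_calibration_record(
    lamp$spectrum, lib, sel, round(lamp$truth_pixels),
    laser = list(mode = "direct", wavelength_nm = 785.142)))
  expect_identical(rec2$coeffs, rec$coeffs)
  expect_identical(rec2$raman_shift_axis, rec$raman_shift_axis)

  # record round-trips through the MAT container
  f <- withr::local_tempfile(fileext = ".mat")
  write_calibration_record(f, rec)
  expect_identical(read_calibration_record(f)$raman_shift_axis,
                   rec$raman_shift_axis)

  expect_error(build_calibration_record(
    lamp$spectrum, lib, sel[1:3], round(lamp$truth_pixels[1:3]),
    laser = list(mode = "direct", wavelength_nm = 785)), "at least 4")
  expect_warning(build_calibration_record(
    lamp$spectrum, lib, sel[1:5], round(lamp$truth_pixels[1:5]),
    laser = list(mode = "direct", wavelength_nm = 785)), "fewer than 6")
})

test_that("axis reconstruction tolerates sub-pixel jitter on refined positions", {
  # 0.2 px Gaussian jitter on 7 refined positions: reconstructed axis
  # within 1 cm-1 RMS of truth over the full detector
  a <- c(9300, 3.2, -1e-4, 1e-8)
  lib <- ne_ar_library()
  sel <- c(1, 9, 17, 26, 34, 43, 52)
  px <- vapply(lib$lines[sel], function(v)
    uniroot(function(p) polyval_asc(a, p) - v, c(0, 1339), tol = 1e-10)$root,
    numeric(1))
  set.seed(42)
  jittered <- px + rnorm(7, 0, 0.2)
  fit <- fit_pixel_to_wavenumber(cbind(jittered, lib$lines[sel]))
  est <- compute_raman_shift_axis(fit, 785.142, 1340)
  tru <- compute_raman_shift_axis(a, 785.142, 1340)
  expect_lt(sqrt(mean((est - tru)^2)), 1)
})
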