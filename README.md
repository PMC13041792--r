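# ramanprep

Reproducible, configuration-driven preprocessing of dispersive Raman
spectra, for labs that acquire on heterogeneous instruments (cart,
portable, Renishaw-class, custom builds) and need one auditable pipeline
instead of per-instrument scripts.

Raw Raman data leave the detector as counts per CCD pixel, contaminated by
electronic offset, instrument spectral response, cosmic rays and broad
autofluorescence. ramanprep covers the full chain from there to a
normalized fingerprint-region spectrum:

* **X-axis calibration** — fits the cubic pixel-to-wavenumber map
  v̄<sub>abs</sub>(p) = a₀ + a₁p + a₂p² + a₃p³ by least squares against a
  bundled 52-line Ne–Ar emission library (9,677.994–12,947.060 cm⁻¹),
  with Savitzky–Golay-derivative peak refinement to sub-pixel centroids.
  The excitation wavelength is entered directly or estimated from a
  measured acetaminophen standard as the mean over certified peaks of
  λᵢ = 10⁷ / (v̄<sub>abs</sub>(pᵢ) + Δv̄<sub>ref,i</sub>), using a bundled
  22-shift certified library (213.3–3326.6 cm⁻¹). The Raman-shift axis is
  Δv̄ = 10⁷/λ<sub>laser</sub> − v̄<sub>abs</sub>, and the calibration is
  persisted as a reloadable MATLAB level-5 record (JSON sidecar optional).
* **Spectral response correction** — a multiplicative factor C(v̄) from a
  white-light measurement against a manufacturer radiance table, from a
  NIST-style certified fifth-order polynomial, or precomputed from file.
* **An eight-stage deterministic pipeline** (P1–P8, fixed order): baseline
  shift to zero, response correction, cosmic-ray placeholder, truncation
  (default 900–1700 cm⁻¹), binning (default 3.5 cm⁻¹, half-open bins,
  mean per bin), optional smoothing, iterative-polynomial (modpoly-style)
  fluorescence background subtraction, and mean/area/max normalization.
* **Declarative execution** — `config.json` (instrument; decides whether
  calibration/response correction run) and `preprocessing.json` (pipeline
  parameters) fully determine a run; schemas are strict, unknown keys are
  errors. Every stage is recorded in a replayable JSON provenance log with
  content hashes, and a batch engine processes file sets with per-file
  fault isolation.
* **Synthetic fixtures** — forward-model generators for lamp,
  acetaminophen, white-light and sample spectra with known ground truth,
  so the whole chain is testable without instrument data.

## Worked example

Calibrate from a (synthetic) Ne–Ar lamp measurement, then run the default
pipeline on a sample spectrum:

```r
library(ramanprep)

lib <- ne_ar_library()
model <- forward_model(baseline_coeffs = 0, seed = 7)   # ground-truth optics
sel <- c(1, 9, 17, 26, 34, 43, 52)                      # seven library lines
lamp <- gen_lamp_spectrum(model, lib, sel)
record <- build_calibration_record(
  lamp$spectrum, lib, sel, approx_pixels = round(lamp$truth_pixels),
  laser = list(mode = "direct", wavelength_nm = 785.142))
record
#> <calibration_record> 1340 pixels, laser 785.1420 nm,
#>   a = [9300, 3.2, -0.0001, 1e-08], 7 reference peaks, 2026-09-28T18:31:35

sample <- gen_sample_spectrum(forward_model(
  peak_shapes = list(list(center = 1003, width = 8, height = 900),
                     list(center = 1450, width = 12, height = 600)),
  baseline_coeffs = c(500, 0.8, -4e-4), noise_sigma = 5, seed = 11))
res <- run_pipeline(sample$spectrum, pipeline_config(), apply_src = FALSE)
res$provenance
#> <provenance_log> 8 entries, input 141ede55.., output 28617f08..
#>   P1 baseline_subtract      applied
#>   P2 apply_src              skipped
#>   P3 cosmic_ray             noop
#>   P4 truncate               applied
#>   P5 bin                    applied
#>   P6 smooth                 skipped
#>   P7 fluorescence_subtract  applied
#>   P8 normalize              applied
res$spectrum
#> <raman_spectrum> 228 points, axis_kind=raman_shift, axis [903.538, 1698.04]
head(as.data.frame(res$spectrum), 3)
#>       axis intensity
#> 1 903.5375  1.638253
#> 2 907.0375  1.540772
#> 3 910.5375  1.392289
```

The recovered calibration reproduces the generating coefficients; the
processed spectrum sits on the bin-centre grid of the 900–1700 cm⁻¹
truncation (first bin centre at the first truncated axis value + 1.75),
with the fluorescence background removed and the mean normalized to 1 —
the two peaks at 1003 and 1450 cm⁻¹ stand on a flat residual baseline.
Intensities are unitless after normalization; hashes identify the exact
input and output for replay.

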