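---
title: "Methods: calibration, response correction and the eight-stage pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibration, response correction and the eight-stage pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanprep)
```

ramanprep turns raw output of a dispersive Raman spectrometer into
normalized fingerprint-region spectra through a fully declarative,
deterministic chain: X-axis calibration, spectral response correction, and
an eight-stage preprocessing pipeline. This vignette is the package's
account of the underlying models, the parameters that matter, the numerical
choices, and what the synthetic test bed does and does not establish.

## The measurement model

A dispersive spectrometer records counts per CCD pixel $p$. The physical
coordinate is the absolute wavenumber of the detected light,
$\tilde\nu_{abs}$ (cm$^{-1}$), related to pixels by the dispersion of the
grating. Over a detector the dispersion is smooth and monotone and is
modelled, as is standard for such instruments, by a cubic:

$$\tilde\nu_{abs}(p) = a_0 + a_1 p + a_2 p^2 + a_3 p^3, \qquad a_1 > 0.$$

Raman spectra are reported against the Raman shift
$\Delta\tilde\nu = 10^7/\lambda_{laser} - \tilde\nu_{abs}$ (cm$^{-1}$,
$\lambda_{laser}$ in nm). Because $\tilde\nu_{abs}$ increases with pixel,
the shift decreases with pixel; `apply_calibration()` reverses the pairing
so every spectrum entering the pipeline has an ascending axis.

## X-axis calibration

Calibration estimates $(a_0..a_3)$ from a measured neon–argon lamp
spectrum. The package bundles a 52-line Ne/Ar emission library spanning
9,677.994–12,947.060 cm$^{-1}$ (`ne_ar_library()`); interior entries are
curated from published NIST Ne/Ar near-infrared line positions, and the
endpoints are fixed by the library's documented span.

Marked peaks are refined to sub-pixel precision by `refine_peak()`: the
first derivative is smoothed with a Savitzky–Golay filter (defaults
window 7, order 2 — wide enough to suppress shot noise on a ~3-pixel-wide
emission line, narrow enough not to merge neighbouring lines), the apex is
the positive-to-negative derivative sign change nearest the user's pick,
the peak span is bounded by the flanking derivative sign changes clipped to
a 15-pixel search half-width, and the refined position is the intensity
centroid $\sum p\,I(p)/\sum I(p)$ over that span. The centroid uses raw
intensities; a constant background therefore pulls it toward the span
centre, which is why calibration lamps should be measured with minimal
background (the noise-robustness test budgets 0.2 px of jitter and still
reconstructs the axis to better than 1 cm$^{-1}$ RMS).

The cubic is fitted by least squares. A cubic in raw pixel indices up to
~2048 is numerically ill-conditioned, so `fit_pixel_to_wavenumber()`
centres and scales pixels internally and transforms the coefficients back
to the raw basis for storage; this is invisible in the results. At least 4
distinct pixels are required (the mathematical minimum); a warning is
issued below 6, since fits through few points extrapolate poorly toward
the detector edges.

The laser wavelength either is entered directly or is estimated from a
measured acetaminophen standard: for each matched certified shift
$\Delta\tilde\nu_{ref,i}$ (22-entry bundled library, 213.3–3326.6
cm$^{-1}$, ASTM-style certified band positions),

$$\lambda_i = \frac{10^7}{\tilde\nu_{abs}(p_i) + \Delta\tilde\nu_{ref,i}},$$

and the estimate is the arithmetic mean over peaks (the per-peak values and
their spread are attached for inspection). The mean is used rather than a
robust location estimate because the per-peak errors are small and
approximately symmetric once peaks are refined; outlying peaks indicate a
mismatched pairing, which should be fixed, not down-weighted.

The calibration record (coefficients, laser wavelength, per-pixel
Raman-shift axis, selected library indices, timestamp) is persisted as a
MATLAB level-5 `.mat` container with variables `wavenumber_axis`,
`laser_wavelength_nm`, `poly_coeffs`, `calibration_datetime`,
`selected_peak_indices` — these names are defined by this package, and a
JSON sidecar with identical field names is written when the path ends in
`.json`. The MAT writer/reader is implemented in the package (doubles and
character arrays, little-endian, uncompressed), sufficient for round trips
and for loading into MATLAB/Octave. Pixel axes are 0-based throughout.

## Spectral response correction

Wavelength-dependent sensitivity of detector and optics is compensated by a
multiplicative factor $C$. Three pathways produce interchangeable
`correction_factor` objects:

* **White light**: the measured broadband-source spectrum is smoothed
  (default Savitzky–Golay, window 15, order 3), its axis converted to
  scattered wavelength $\lambda = 10^7/(10^7/\lambda_{laser} -
  \Delta\tilde\nu)$, a polynomial (default order 5, matching the
  certified-material convention) is fitted to the manufacturer radiance
  table and evaluated on that axis, both profiles are scaled to 1 at a
  common centre wavelength, and $C$ is their pointwise ratio.
* **Certified reference material**: the true profile is the certified
  fifth-order polynomial evaluated in the certificate's explicit variable
  convention (different standards define the quintic in different
  variables, so the convention is a required field); the ratio is smoothed
  after division.
* **Precomputed**: loaded from two-column text/CSV or a spreadsheet.

The normalization point defaults to the sample nearest the axis midpoint;
because both profiles are scaled there, $C$ is defined up to that centre
constant, which cancels in any subsequently normalized spectrum.
Extrapolation is refused everywhere: the radiance table must cover the
converted span, and `resample_factor()` (linear interpolation) declines
targets outside the factor's axis.

## The eight-stage pipeline

Stages run in a fixed, non-configurable order; configurations only toggle
whether P2 and P6 act, and every stage — applied, skipped or no-op — is
recorded in the provenance log.

| Stage | Operation | Parameters (defaults) |
|---|---|---|
| P1 | baseline shift to zero | — |
| P2 | multiply by response factor | `apply_src` (true; effective only if the system requires correction) |
| P3 | cosmic-ray placeholder (no-op) | — |
| P4 | truncation, closed interval | 900–1700 cm$^{-1}$ |
| P5 | binning, half-open bins | width 3.5 cm$^{-1}$ |
| P6 | smoothing | none / savgol / moving average / median |
| P7 | fluorescence background subtraction | order 5, ≤100 iterations, tol 1e-4 |
| P8 | normalization | mean (also area, max) |

Conventions that the formulas alone do not fix, chosen once and tested:

* **P4** keeps both endpoints (a closed interval matches the usual reading
  of a "900–1700" range).
* **P5** anchors bins at the first truncated axis value, uses half-open
  intervals $[v_0 + k\Delta b,\, v_0 + (k+1)\Delta b)$, averages members,
  reports bin centres, and keeps a trailing partial bin. An empty interior
  bin means the input grid is coarser than the bin width and is an error
  rather than a silent interpolation. With the defaults (900–1700,
  3.5 cm$^{-1}$) a dense input yields 229 bins.
* **P7** is the modpoly-style lower-envelope iteration: fit a polynomial of
  the requested order, replace the working curve by the pointwise minimum
  of itself and the fit, repeat. The paperless detail is the stopping
  rule: iteration ends when the sup-norm change drops below
  `tolerance × (max − min)` of the input or at `max_iterations`. Fits use
  an axis mapped to $[-1,1]$ for conditioning.
* **P8** mean normalization divides by the arithmetic mean (output mean
  exactly 1); area normalization uses the trapezoidal integral over the
  axis; max normalization divides by the maximum.
* **P6** defaults to `none`: smoothing is an explicit analytic choice, and
  defaulting it on would be a hidden transformation.

Determinism is structural: `run_pipeline()` is a pure function of the
spectrum, the configuration and the correction factor, verified by content
hashes (SHA-256 over a canonical 17-significant-digit serialization, which
is platform-stable because it round-trips IEEE doubles exactly).

## Configurations, execution paths, batch

Two JSON documents fully determine execution. `config.json` describes the
instrument and whether it needs calibration and response correction
(Renishaw-class systems deliver calibrated spectra, so both default off
there; the open `custom` kind must state both flags). `preprocessing.json`
holds exactly the pipeline parameters above. Loading is strict: unknown
keys — including misspellings and any attempt to introduce a stage-ordering
key — are errors, and absent keys take only the documented defaults.
JSON-Schema documents for both files ship under `inst/schemas/`.

The batch engine runs every file through the same `process_one()`
implementation as the single-spectrum and preview paths (batch/single hash
equality is tested, not assumed). Failures are isolated per file and
reported by name. Output names embed the key parameters and a timestamp,
`<stem>__s<start>_e<stop>_b<width>_n<norm>__<UTC-timestamp>.txt`, and each
output carries a JSON provenance sidecar embedding the configuration
snapshots, the correction curve, and input/output hashes —
`replay_provenance()` re-executes a run from the sidecar alone and verifies
the recorded output hash.

## The synthetic test bed

`forward_model()` emulates the measurement chain with known ground truth:
a monotone cubic dispersion (default $a = (9300, 3.2, -10^{-4}, 10^{-8})$
over 1340 pixels — chosen so the detector covers both bundled reference
libraries at 785 nm-class excitation), an excitation wavelength (default
785.142 nm), Gaussian/Lorentzian peaks, a polynomial background, a smooth
multiplicative response gain, additive Gaussian noise, and isolated
cosmic-ray spikes. Lamp and acetaminophen generators place peaks at the
exact dispersion roots of library lines (bracketed root-finding, tolerance
1e-10 px) and return those roots as truth; the white-light generator uses a
smooth positive cubic radiance profile so the order-5 table fit introduces
no model error; sample generators return every additive component.

Problem sizes are kept small enough that the full suite runs in seconds:
1340-pixel detectors, 7–22 peaks per calibration, batches of ≤7 files,
and Monte-Carlo loops of 10–20 draws under fixed seeds.

What passing tests show — and what they do not: the generators share the
package's forward conventions (axis construction, peak placement), so the
suite validates the *processing chain* against analytically known inputs.
It does not validate against real detector effects: Poisson shot noise
(the optional noise model is Gaussian), detector nonlinearity, wavelength
drift within a session, peak-shape asymmetry, or vendor binary formats are
all outside the model, and results on real instruments depend on those.

## Known limitations

* The min-update envelope estimator in P7 carries a systematic off-peak
  bias that grows with band width relative to the fitted window: the test
  suite verifies it stays below 1% of peak height for a narrow band
  (2 cm$^{-1}$ sigma) and below 10% for a broad 12 cm$^{-1}$ band over the
  default fingerprint window, with the implementation agreeing with an
  independent reimplementation of the iteration to 1e-6. Broad, intense
  bands therefore leave a small residual pedestal; narrower fitting
  windows or higher orders reduce it at the cost of baseline fidelity.
* P3 is deliberately a recorded no-op: cosmic-ray removal is reserved
  pipeline structure, not implemented behaviour. Spikes survive to P5,
  where binning dilutes but does not remove them.
* Peak-to-line matching is user-supplied; the package does not attempt
  automatic assignment, so a mispaired pick produces a poor fit rather
  than a diagnosis.
* The MAT container support is intentionally minimal (uncompressed
  little-endian level-5, doubles and strings); it reads files this package
  writes, not arbitrary MAT files.
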