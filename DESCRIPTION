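Package: ramanprep
Title: Reproducible, Configuration-Driven Raman Spectral Preprocessing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for Raman spectral preprocessing across
    heterogeneous instruments. Provides pixel-to-wavenumber X-axis
    calibration against bundled neon-argon emission and acetaminophen
    Raman-shift reference libraries, excitation-wavelength estimation,
    spectral response correction (white-light, certified-reference-material,
    or precomputed correction factors), and a deterministic eight-stage
    preprocessing pipeline (baseline shift, response correction, cosmic-ray
    placeholder, truncation, binning, smoothing, iterative-polynomial
    fluorescence background subtraction, normalization). Execution is driven
    by declarative JSON configuration files; every operation is recorded in
    a replayable provenance log, and a batch engine processes file sets with
    per-file fault isolation. Synthetic forward-model generators emulate
    lamp, acetaminophen, white-light and sample spectra with known ground
    truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    digest,
    readxl,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    zip
Config/testthat/edition: 3
RoxygenNote: 7.3.3
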