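# Shared fixture builders. All synthetic data is generated in code at test
# time; nothing binary is stored in the repository.

# canonical two-peak biological-style sample model on the default instrument
sample_model <- function(seed = 1L, noise_sigma = 5) {
  forward_model(
    peak_shapes = list(list(center = 1003, width = 8, height = 900),
                       list(center = 1450, width = 12, height = 600)),
    baseline_coeffs = c(500, 0.8, -4e-4),
    noise_sigma = noise_sigma, seed = seed)
}

write_sample_files <- function(dir, n = 7L, seed0 = 100L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(seq_len(n), function(i) {
    s <- gen_sample_spectrum(sample_model(seed = seed0 + i))$spectrum
    path <- file.path(dir, sprintf("sample_%02d.txt", i))
    write_processed_spectrum(path, s)
    path
  }, character(1))
}

uncalibrated_system <- function() {
  system_config("custom", excitation_wavelength_nm = 785.142,
                requires_calibration = FALSE, requires_src = FALSE)
}

# minimal single-sheet xlsx with two numeric columns (inline strings are not
# needed; numbers are stored as plain <v> values). Used to cross-check the
# spreadsheet branch of read_correction_factor against the text branch.
write_minimal_xlsx <- function(path, col1, col2) {
  stopifnot(length(col1) == length(col2))
  dir <- tempfile("xlsxsrc")
  dir.create(file.path(dir, "_rels"), recursive = TRUE)
  dir.create(file.path(dir, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(dir, "xl", "worksheets"), recursive = TRUE)
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    '</Types>'), file.path(dir, "[Content_Types].xml"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'), file.path(dir, "_rels", ".rels"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="Sheet1" sheetId="1" r:id="rId1"/></sheets>',
    '</workbook>'), file.path(dir, "xl", "workbook.xml"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    '</Relationships>'), file.path(dir, "xl", "_rels", "workbook.xml.rels"))
  rows <- vapply(seq_along(col1), function(i) {
    sprintf('<row r="%d"><c r="A%d"><v>%.17g</v></c><c r="B%d"><v>%.17g</v></c></row>',
            i, i, col1[i], i, col2[i])
  }, character(1))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', rows, '</sheetData></worksheet>'),
    file.path(dir, "xl", "worksheets", "sheet1.xml"))
  old <- setwd(dir)
  on.exit(setwd(old))
  zip::zip(path, files = c("[Content_Types].xml", "_rels/.rels",
                           "xl/workbook.xml", "xl/_rels/workbook.xml.rels",
                           "xl/worksheets/sheet1.xml"))
  invisible(path)
}
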