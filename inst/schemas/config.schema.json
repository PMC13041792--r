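{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ramanprep system configuration (config.json)",
  "description": "Instrument description controlling which workflow stages run. Unknown keys are rejected by the loader; no silent defaulting beyond the documented defaults.",
  "type": "object",
  "additionalProperties": false,
  "required": ["system", "excitation_wavelength_nm"],
  "properties": {
    "system": {
      "enum": ["Cart", "Portable", "Renishaw", "MANTIS", "custom"],
      "description": "Instrument family. Renishaw-class systems deliver calibrated spectra: requires_calibration and requires_src default to false there, true elsewhere; 'custom' must state both flags explicitly."
    },
    "excitation_wavelength_nm": {"type": "number", "exclusiveMinimum": 0},
    "detector": {"type": "string"},
    "probe": {"type": "string"},
    "spectral_range": {
      "type": "array", "items": {"type": "number"},
      "minItems": 2, "maxItems": 2,
      "description": "Covered Raman-shift interval, cm-1, increasing."
    },
    "ccd_x": {"type": "integer", "minimum": 2},
    "ccd_y": {"type": "integer", "minimum": 1},
    "requires_calibration": {"type": "boolean"},
    "requires_src": {"type": "boolean"}
  }
}
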