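{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ramanprep pipeline configuration (preprocessing.json)",
  "description": "Parameterization of the fixed P1-P8 preprocessing chain. Stage order is immutable and not configurable. Unknown keys are rejected; absent keys take the documented defaults shown here.",
  "type": "object",
  "additionalProperties": false,
  "properties": {
    "truncate_start": {"type": "number", "default": 900,
      "description": "P4 lower bound, cm-1 (closed interval)."},
    "truncate_stop": {"type": "number", "default": 1700,
      "description": "P4 upper bound, cm-1 (closed interval)."},
    "bin_width": {"type": "number", "exclusiveMinimum": 0, "default": 3.5,
      "description": "P5 bin width, cm-1; half-open bins anchored at the first truncated axis value."},
    "smoothing": {
      "type": "object", "additionalProperties": false,
      "properties": {
        "method": {"enum": ["savgol", "moving_average", "median", "none"],
                   "default": "none"},
        "window": {"type": "integer", "minimum": 3,
                   "description": "Odd window length."},
        "polyorder": {"type": "integer", "minimum": 0,
                      "description": "Savitzky-Golay order, < window."}
      }
    },
    "fbs": {
      "type": "object", "additionalProperties": false,
      "properties": {
        "poly_order": {"type": "integer", "minimum": 0, "default": 5},
        "max_iterations": {"type": "integer", "minimum": 1, "default": 100},
        "tolerance": {"type": "number", "minimum": 0, "default": 1e-4}
      }
    },
    "normalization": {"enum": ["mean", "area", "max"], "default": "mean"},
    "apply_src": {"type": "boolean", "default": true,
      "description": "P2 switch; effective only when the system configuration requires spectral response correction."},
    "cosmic_ray": {"enum": ["none"], "default": "none",
      "description": "P3 is a recorded no-op placeholder."}
  }
}
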