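{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "copperhvl analysis report",
  "type": "object",
  "required": ["results", "margin_mmcu", "alpha"],
  "properties": {
    "results": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["scanner", "tube_voltage_kv", "method", "hvl_mmcu",
                     "effective_energy_kev", "r_squared"],
        "properties": {
          "scanner": {"type": "string"},
          "tube_voltage_kv": {"type": "number"},
          "method": {"type": "string"},
          "hvl_mmcu": {"type": "number"},
          "effective_energy_kev": {"type": "number"},
          "r_squared": {"type": "number"}
        }
      }
    },
    "comparisons": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["method_a", "method_b", "n", "mean_diff_mmcu",
                     "sd_diff_mmcu", "mean_abs_diff_mmcu", "p_tost",
                     "margin_mmcu"],
        "properties": {
          "method_a": {"type": "string"},
          "method_b": {"type": "string"},
          "n": {"type": "number"},
          "mean_diff_mmcu": {"type": "number"},
          "sd_diff_mmcu": {"type": "number"},
          "mean_abs_diff_mmcu": {"type": "number"},
          "p_tost": {"type": "number"},
          "margin_mmcu": {"type": "number"}
        }
      }
    },
    "margin_mmcu": {"type": "number"},
    "alpha": {"type": "number"}
  }
}
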