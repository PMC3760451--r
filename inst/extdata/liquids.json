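{
  "comment": "Standard vOCG probe liquid surface tension components (mJ/m^2); same values as the package defaults, provided as an example override file.",
  "liquids": [
    {"liquid": "water", "gamma_total": 72.8, "gamma_lw": 21.8, "gamma_plus": 25.5, "gamma_minus": 25.5},
    {"liquid": "glycerol", "gamma_total": 64.0, "gamma_lw": 34.0, "gamma_plus": 3.92, "gamma_minus": 57.4},
    {"liquid": "diiodomethane", "gamma_total": 50.8, "gamma_lw": 50.8, "gamma_plus": 0, "gamma_minus": 0}
  ]
}
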