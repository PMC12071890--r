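{
  "_comment": "Default Lyman-Kutcher-Burman parameters per endpoint (classical Burman/Emami-lineage values). Defaults: override with institution-specific parameter sets where available.",
  "endpoints": [
    {"endpoint": "heart_pericarditis", "structure": "heart", "td50_gy": 48.0, "m": 0.10, "n": 0.35},
    {"endpoint": "lung_pneumonitis", "structure": "lung_total", "td50_gy": 24.5, "m": 0.18, "n": 0.87},
    {"endpoint": "esophagus_perforation", "structure": "esophagus", "td50_gy": 68.0, "m": 0.11, "n": 0.06}
  ]
}
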