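{
  "version": 1,
  "seed": 3,
  "survey_n": 120,
  "discount": 0.03,
  "metric": "DALY",
  "psa": {"enabled": true, "n_draws": 50},
  "expansion": {"enabled": false},
  "scenarios": [
    {"label": "Mandatory salt limits",
     "components": [{"ref": "mandatory_salt"}]},
    {"label": "Thiazide diuretic (ge15)",
     "components": [{"ref": "thiazide", "bands": ["ge15"]}]},
    {"label": "Current practice",
     "components": [
       {"ref": "voluntary_salt"},
       {"ref": "bp_current", "bands": ["5-9", "10-14", "ge15"], "uptake": 0.35},
       {"ref": "lipid_current", "bands": ["5-9", "10-14", "ge15"], "uptake": 0.25},
       {"ref": "dietary_advice", "bands": ["5-9", "10-14", "ge15"], "uptake": 0.20}
     ]}
  ]
}
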