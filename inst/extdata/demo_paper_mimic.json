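{
  "version": 1,
  "seed": 2008,
  "survey_n": 500,
  "discount": 0.03,
  "metric": "DALY",
  "gp_attendance": 0.85,
  "assessment_participation": 0.70,
  "statin_price": "australia",
  "psa": {"enabled": true, "n_draws": 200},
  "expansion": {"enabled": true, "threshold": 50000},
  "scenarios": [
    {"label": "Mandatory salt limits (all risk levels)",
     "components": [{"ref": "mandatory_salt"}]},
    {"label": "Community heart health program (all risk levels)",
     "components": [{"ref": "community_program"}]},
    {"label": "Thiazide diuretic (ge15% risk)",
     "components": [{"ref": "thiazide", "bands": ["ge15"]}]},
    {"label": "Calcium channel blocker (ge15% risk)",
     "components": [{"ref": "ccb", "bands": ["ge15"]}]},
    {"label": "ACE inhibitor (ge15% risk)",
     "components": [{"ref": "ace_inhibitor", "bands": ["ge15"]}]},
    {"label": "Beta-blocker (ge15% risk)",
     "components": [{"ref": "beta_blocker", "bands": ["ge15"]}]},
    {"label": "Aspirin (ge15% risk)",
     "components": [{"ref": "aspirin", "bands": ["ge15"]}]},
    {"label": "Statin (ge15% risk)",
     "components": [{"ref": "statin", "bands": ["ge15"]}]},
    {"label": "Dietary advice (ge15% risk)",
     "components": [{"ref": "dietary_advice", "bands": ["ge15"]}]},
    {"label": "Lifestyle program (ge15% risk)",
     "components": [{"ref": "lifestyle_program", "bands": ["ge15"]}]},
    {"label": "Phytosterol margarine (ge15% risk)",
     "components": [{"ref": "phytosterol", "bands": ["ge15"]}]},
    {"label": "Current practice",
     "components": [
       {"ref": "voluntary_salt"},
       {"ref": "bp_current", "bands": ["5-9", "10-14", "ge15"], "uptake": 0.35},
       {"ref": "lipid_current", "bands": ["5-9", "10-14", "ge15"], "uptake": 0.25},
       {"ref": "dietary_advice", "bands": ["5-9", "10-14", "ge15"], "uptake": 0.20}
     ]},
    {"label": "Cost-effective package",
     "components": [
       {"ref": "mandatory_salt"},
       {"ref": "thiazide", "bands": ["5-9", "10-14", "ge15"]},
       {"ref": "ccb", "bands": ["5-9", "10-14", "ge15"]},
       {"ref": "ace_inhibitor", "bands": ["5-9", "10-14", "ge15"]}
     ]}
  ]
}
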