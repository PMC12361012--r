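{
  "seed": 20260910,
  "simulation": {
    "n_items": 20,
    "n_respondents": 300,
    "n_panelists": 10,
    "placement_noise_sd": 2.5
  },
  "vignettes": { "n_vignettes": 8, "n_items": 6 },
  "gcpsr": { "gate": "chronic_pain" }
}
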