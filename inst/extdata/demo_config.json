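{
  "seed": 11,
  "out_dir": "demo_out",
  "data": {
    "simulate": {
      "scenario": "strong",
      "n_pairs": 12,
      "n_flipped": 5,
      "n_blocks": 4,
      "n_controls": 20,
      "n_patients": 20,
      "timepoints": 120
    }
  },
  "community": { "k": 6, "trials": 50 },
  "selection": { "n_edges": 30, "resamples": 20 },
  "classify": {
    "feature_sets": ["K_edges", "rho", "K_plus_rho"],
    "scheme": ["split50"],
    "repeats": 20
  }
}
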