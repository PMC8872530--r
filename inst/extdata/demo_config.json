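{
  "seed": 1,
  "panel": {
    "n_sites": 20000,
    "freq_min": 0.05,
    "freq_max": 0.95
  },
  "kinship": {
    "relationship": "same_individual",
    "n_covered_a": 1500,
    "n_covered_b": 3000,
    "overlap_correlation": 0.55,
    "error_rate": 0.01,
    "error_grid": [0, 0.005, 0.01, 0.02],
    "n_replicates": 500
  },
  "sexing": {
    "sex": "female",
    "total_reads": 100000
  },
  "mito": {
    "reference_length": 16569,
    "rotation_origin": 8284,
    "spacer_len": 14,
    "depth_target": 60,
    "mean_length_bp": 60,
    "deamination_rate": 0.02,
    "prop_low_mq": 0.05,
    "dup_rate": 0.05
  }
}
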