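{
  "id": "two-category-null",
  "population": {
    "categories": [
      {"label": "responders", "weight": 0.5,
       "arm0": {"family": "normal", "mean": 0, "sd": 1},
       "arm1": {"family": "normal", "mean": 0, "sd": 1}},
      {"label": "nonresponders", "weight": 0.5,
       "arm0": {"family": "normal", "mean": 1, "sd": 1},
       "arm1": {"family": "normal", "mean": 1, "sd": 1}}
    ],
    "dependence": {"mode": "independent", "icc": 0}
  },
  "design": {"n": 40, "allocation": "complete-balanced", "regime": "fixed"},
  "method": "parametric",
  "hypothesis": "null",
  "n_reps": 500
}
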