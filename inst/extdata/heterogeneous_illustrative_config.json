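{
  "id": "heterogeneous-illustrative",
  "_comment": "Illustrative only: a many-category cohort with bimodal, dormancy-like survival surrogates (cured vs relapsing strata). No claim of biological fidelity.",
  "population": {
    "categories": [
      {"label": "no-occult-mets-cured", "weight": 0.35,
       "arm0": {"family": "truncated-normal", "mean": 9, "sd": 1, "lower": 5, "upper": 12},
       "arm1": {"family": "truncated-normal", "mean": 9, "sd": 1, "lower": 5, "upper": 12}},
      {"label": "dormant-mets-late-relapse", "weight": 0.25,
       "arm0": {"family": "truncated-normal", "mean": 6, "sd": 1.5, "lower": 1, "upper": 12},
       "arm1": {"family": "truncated-normal", "mean": 6, "sd": 1.5, "lower": 1, "upper": 12}},
      {"label": "dormant-mets-triggered", "weight": 0.15,
       "arm0": {"family": "truncated-normal", "mean": 3, "sd": 1, "lower": 0.5, "upper": 8},
       "arm1": {"family": "truncated-normal", "mean": 3, "sd": 1, "lower": 0.5, "upper": 8}},
      {"label": "aggressive-occult-tumors", "weight": 0.15,
       "arm0": {"family": "truncated-normal", "mean": 1.5, "sd": 0.7, "lower": 0.1, "upper": 5},
       "arm1": {"family": "truncated-normal", "mean": 1.5, "sd": 0.7, "lower": 0.1, "upper": 5}},
      {"label": "nonresponder-stable", "weight": 0.10,
       "arm0": {"family": "uniform", "min": 2, "max": 10},
       "arm1": {"family": "uniform", "min": 2, "max": 10}}
    ],
    "dependence": {"mode": "independent", "icc": 0}
  },
  "design": {"n": 200, "allocation": "permuted-block", "block_length": 4,
             "regime": "fixed"},
  "method": "parametric",
  "hypothesis": "null",
  "n_reps": 1000
}
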