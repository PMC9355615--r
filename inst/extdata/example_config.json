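{
  "simulate": {
    "regime": "heterogeneous_selection",
    "n_sites": 10,
    "quadrats_per_site": 1,
    "depths": ["surface"],
    "reads_per_sample": 2000,
    "niche_breadth": 0.1,
    "n_otus": 300,
    "seed": 1
  },
  "n_null": 999,
  "n_perm": 999,
  "alpha": 0.05,
  "seed": 1
}
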