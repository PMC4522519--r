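{
  "model": {
    "family": {"type": "rotation", "a": 0, "b": 0.75},
    "interaction": {"type": "controlled_rotation", "mu": [-0.3927, 0.3927]},
    "rho0": "basis",
    "sigma0": "neutral",
    "reset_sigma": false
  },
  "context": {"preset": "clockwise", "n_angles": 11},
  "experiment": {
    "groups": {"A": 55, "B": 48, "C": 48},
    "contexts": {"A": "random", "B": "clockwise", "C": "counterclockwise"},
    "n_pictures": 11
  },
  "seed": 1
}
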