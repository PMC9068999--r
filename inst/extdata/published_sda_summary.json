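{
  "eigenvalues": [2.178, 1.538, 0.838, 0.518],
  "n": 245,
  "p": 21,
  "g": 5,
  "roi_counts": {
    "control": 50,
    "SPS1d": 50,
    "SPS4d": 50,
    "SPS7d": 45,
    "SPS14d": 50
  },
  "features_per_roi": 262
}
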