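{
  "groups": ["SPS1d", "SPS4d"],
  "positive": "SPS4d",
  "intercept": -11.77,
  "coefficients": {
    "MinNorm": 0.06278,
    "S(2,0)SumOfSqs": 0.009153,
    "S(2,-2)SumOfSqs": 0.01334,
    "S(3,-3)Correlat": 0.1802,
    "S(3,-3)SumVarnc": 0.0006736,
    "S(4,-4)Contrast": -0.0004929,
    "S(5,0)SumOfSqs": -0.002089,
    "S(5,0)InvDfMom": -5.44,
    "S(5,0)DifVarnc": -0.0002695,
    "GrSkewness": 0.05052
  },
  "lambda": 0.05,
  "log_lambda": -2.99573227355399
}
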