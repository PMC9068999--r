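{
  "groups": ["SPS4d", "SPS14d"],
  "positive": "SPS14d",
  "intercept": -7.73,
  "coefficients": {
    "MinNorm": 0.142,
    "Skewness": -1.296,
    "S(2,0)DifEntrp": -1.964,
    "S(2,2)InvDfMom": 7.538,
    "S(2,2)DifVarnc": 0.007,
    "S(2,-2)Correlat": 2.366,
    "S(2,-2)SumAverg": -0.127,
    "S(0,3)InvDfMom": 1.492,
    "S(3,3)DifVarnc": 0.001,
    "S(3,-3)SumAverg": -0.19,
    "S(4,-4)Correlat": 0.416,
    "S(4,-4)SumEntrp": 1.088,
    "S(5,0)InvDfMom": -1.22,
    "S(5,0)Entropy": 0.953,
    "S(5,0)DifVarnc": -0.026,
    "S(0,5)Contrast": -0.005,
    "S(0,5)Correlat": 0.299,
    "S(0,5)DifVarnc": -0.001,
    "S(5,5)SumVarnc": 0.002,
    "Horzl_LngREmph": 2.157
  },
  "lambda": 0.019,
  "log_lambda": -3.9633162998157
}
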