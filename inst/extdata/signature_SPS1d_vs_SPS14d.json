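{
  "groups": ["SPS1d", "SPS14d"],
  "positive": "SPS14d",
  "intercept": 23.514,
  "coefficients": {
    "Skewness": -0.45,
    "S(1,0)DifEntrp": -11.303,
    "S(1,1)InvDfMom": -7.96,
    "S(1,-1)InvDfMom": -7.592,
    "S(2,0)SumAverg": -0.484,
    "S(0,2)DifVarnc": -0.083,
    "S(2,2)InvDfMom": 2.953,
    "S(2,2)DifVarnc": 0.013,
    "S(0,3)SumOfSqs": -0.025,
    "S(0,3)InvDfMom": 22.303,
    "S(3,3)DifVarnc": 0.013,
    "S(4,0)DifVarnc": -0.001,
    "S(0,4)DifVarnc": -0.029,
    "S(4,4)Entropy": -2.369,
    "S(5,0)SumVarnc": 0.027,
    "S(5,0)Entropy": 3.405,
    "S(0,5)DifVarnc": -0.014,
    "S(5,5)Contrast": -0.007,
    "S(5,5)SumVarnc": 0.003,
    "S(5,5)SumEntrp": 3.423,
    "S(5,5)DifVarnc": 0.016,
    "S(5,-5)SumOfSqs": 0.004,
    "S(5,-5)DifVarnc": 0.002,
    "Horzl_LngREmph": 3.061,
    "GrVariance": -0.156,
    "Teta1": 2.438,
    "Teta2": -5.445
  },
  "lambda": 0.013,
  "log_lambda": -4.3428059215206
}
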