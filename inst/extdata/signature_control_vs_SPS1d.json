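{
  "groups": ["control", "SPS1d"],
  "positive": "SPS1d",
  "intercept": -26.323,
  "coefficients": {
    "S(1,0)SumAverg": -0.113,
    "S(1,0)SumEntrp": 0.678,
    "S(0,1)SumEntrp": 0.423,
    "S(2,0)InvDfMom": 4.703,
    "S(0,2)Correlat": -2.241,
    "S(0,2)InvDfMom": -5.431,
    "S(2,2)DifVarnc": -0.008,
    "S(2,-2)Contrast": 0.007,
    "S(4,0)InvDfMom": -15.567,
    "S(4,4)InvDfMom": -2.478,
    "S(4,-4)DifEntrp": 3.256,
    "S(5,0)Contrast": -0.003,
    "S(5,0)Correlat": 0.18,
    "S(5,0)InvDfMom": 1.569,
    "S(5,0)SumAverg": 0.011,
    "S(0,5)DifVarnc": 0.03,
    "S(5,5)SumAverg": 0.039,
    "S(5,5)SumEntrp": 4.152,
    "S(5,-5)SumVarnc": -0.002,
    "45dgr_RLNonUni": 0.123,
    "GrNonZeros": 9.046
  },
  "lambda": 0.02,
  "log_lambda": -3.91202300542815
}
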