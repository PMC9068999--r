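{
  "groups": ["control", "SPS7d"],
  "positive": "SPS7d",
  "intercept": -48.294,
  "coefficients": {
    "MinNorm": 0.104,
    "Kurtosis": 0.153,
    "S(1,1)InvDfMom": -2.713,
    "S(1,1)DifVarnc": 0.085,
    "S(1,-1)Contrast": -0.002,
    "S(1,-1)InvDfMom": 14.507,
    "S(3,-3)InvDfMom": 0.354,
    "S(4,0)InvDfMom": -2.992,
    "S(5,0)InvDfMom": -4.858,
    "S(5,0)SumAverg": 0.201,
    "S(0,5)DifVarnc": 0.003,
    "S(5,5)DifVarnc": 0.002,
    "GrNonZeros": 14.086,
    "Teta3": 2.679
  },
  "lambda": 0.025,
  "log_lambda": -3.68887945411394
}
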