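{
  "groups": ["SPS1d", "SPS7d"],
  "positive": "SPS7d",
  "intercept": -9.741,
  "coefficients": {
    "S(1,0)DifEntrp": -0.121,
    "S(1,1)SumVarnc": 0.001,
    "S(1,-1)Correlat": 1.926,
    "S(2,0)InvDfMom": -2.477,
    "S(2,0)DifVarnc": -0.027,
    "S(2,2)Correlat": 0.179,
    "S(2,2)InvDfMom": 12.293,
    "S(0,3)InvDfMom": 6.702,
    "S(3,3)SumAverg": -0.049,
    "S(0,4)InvDfMom": 18.735,
    "S(5,0)Contrast": 0.003,
    "S(5,0)InvDfMom": -1.416,
    "S(0,5)InvDfMom": 3.21,
    "S(0,5)DifVarnc": -0.004,
    "S(5,-5)InvDfMom": 1.655,
    "S(5,-5)SumAverg": 0.038,
    "Teta2": -3.01,
    "Teta4": -4.267
  },
  "lambda": 0.033,
  "log_lambda": -3.41124771751566
}
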