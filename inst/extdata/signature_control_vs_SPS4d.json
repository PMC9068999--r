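{
  "groups": ["control", "SPS4d"],
  "positive": "SPS4d",
  "intercept": -44.87,
  "coefficients": {
    "S(1,0)SumAverg": -0.1795,
    "S(0,1)Correlat": -1.47,
    "S(2,0)InvDfMom": 21.81,
    "S(2,0)DifEntrp": 2.942,
    "S(0,2)InvDfMom": -4.939,
    "S(0,2)SumVarnc": -0.0004707,
    "S(2,2)SumOfSqs": -0.01966,
    "S(2,2)DifVarnc": -0.01453,
    "S(2,-2)SumVarnc": -0.007999,
    "S(3,0)InvDfMom": -6.434,
    "S(3,3)DifVarnc": -0.01026,
    "S(4,0)InvDfMom": -10.61,
    "S(4,4)InvDfMom": -2.443,
    "S(4,-4)DifEntrp": 6.212,
    "S(5,0)Contrast": -0.006959,
    "S(0,5)DifVarnc": 0.0106,
    "S(5,5)SumEntrp": 1.823,
    "Horzl_LngREmph": 0.02518,
    "Vertl_RLNonUni": 0.0193,
    "45dgr_Fraction": 45.65,
    "135dr_ShrtREmp": -11.5,
    "GrMean": 1.516,
    "GrNonZeros": 15.11
  },
  "lambda": 0.015,
  "log_lambda": -4.19970507787993
}
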