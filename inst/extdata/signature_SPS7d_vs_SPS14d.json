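{
  "groups": ["SPS7d", "SPS14d"],
  "positive": "SPS14d",
  "intercept": 20.2,
  "coefficients": {
    "S(1,0)InvDfMom": 1.655,
    "S(1,1)Contrast": -0.001581,
    "S(1,-1)InvDfMom": -17.15,
    "S(2,0)SumOfSqs": -0.01771,
    "S(2,0)InvDfMom": 23.94,
    "S(0,2)InvDfMom": -11.1,
    "S(2,2)SumOfSqs": -0.00878,
    "S(3,0)DifVarnc": 0.009913,
    "S(3,3)InvDfMom": -3.492,
    "S(0,4)InvDfMom": -8.386,
    "S(4,-4)Correlat": 0.009364,
    "S(4,-4)SumVarnc": 0.0009205,
    "S(5,0)Correlat": 0.656,
    "S(5,0)InvDfMom": 12.03,
    "S(5,0)SumVarnc": 0.003034,
    "S(0,5)DifVarnc": -0.04283,
    "S(5,5)Entropy": -1.489,
    "S(5,5)DifEntrp": -0.9448,
    "Horzl_LngREmph": 0.6066,
    "Teta1": 0.1758,
    "Teta3": -2.076
  },
  "lambda": 0.022,
  "log_lambda": -3.81671282562382
}
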