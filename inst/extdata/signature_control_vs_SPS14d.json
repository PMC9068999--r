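{
  "groups": ["control", "SPS14d"],
  "positive": "SPS14d",
  "intercept": -25.11,
  "coefficients": {
    "MinNorm": 0.08246,
    "S(2,0)InvDfMom": 0.03396,
    "S(2,0)SumAverg": -0.04167,
    "S(0,2)InvDfMom": -5.022,
    "S(2,2)SumVarnc": -0.004633,
    "S(2,-2)SumAverg": -0.003943,
    "S(3,-3)SumAverg": -0.04006,
    "S(4,0)InvDfMom": -18.27,
    "S(4,0)DifVarnc": -0.005782,
    "S(5,0)Correlat": 1.598,
    "S(5,0)SumAverg": 0.1341,
    "S(5,0)SumVarnc": 0.001653,
    "S(5,0)DifVarnc": -0.007598,
    "S(5,5)Contrast": -0.0002789,
    "S(5,5)DifVarnc": -0.002237,
    "Horzl_LngREmph": 1.75,
    "45dgr_ShrtREmp": 10.58
  },
  "lambda": 0.031,
  "log_lambda": -3.47376807449699
}
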