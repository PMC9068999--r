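{
  "groups": ["SPS4d", "SPS7d"],
  "positive": "SPS7d",
  "intercept": -26.622,
  "coefficients": {
    "MinNorm": 0.132,
    "Perc.01%": 0.028,
    "S(0,1)InvDfMom": 0.524,
    "S(1,-1)Correlat": 0.525,
    "S(1,-1)SumVarnc": 0.008,
    "S(1,-1)DifEntrp": -0.297,
    "S(0,2)InvDfMom": 12.687,
    "S(2,2)InvDfMom": 2.753,
    "S(0,3)InvDfMom": 0.302,
    "S(4,4)SumEntrp": -0.536,
    "S(4,4)DifVarnc": 0.019,
    "S(5,0)InvDfMom": -27.167,
    "S(5,0)SumAverg": 0.079,
    "S(5,5)DifVarnc": 0.001,
    "S(5,-5)InvDfMom": 2.816,
    "Horzl_ShrtREmp": -11.808,
    "45dgr_RLNonUni": -0.073,
    "GrKurtosis": -0.236,
    "GrNonZeros": 5.767,
    "Teta2": -0.274,
    "Teta3": 4.306
  },
  "lambda": 0.014,
  "log_lambda": -4.26869794936688
}
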