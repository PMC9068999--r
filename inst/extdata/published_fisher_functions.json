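{
  "features": ["Perc.10%", "S(1,0)InvDfMom", "S(0,1)DifEntrp", "S(1,-1)Entropy", "S(2,0)InvDfMom", "S(2,0)SumAverg", "S(3,0)AngScMom", "S(3,3)Correlat", "S(3,3)DifVarnc", "S(4,0)Contrast", "S(4,0)InvDfMom", "S(4,0)DifVarnc", "S(0,4)DifEntrp", "S(4,4)AngScMom", "S(4,-4)SumEntrp", "S(5,0)Correlat", "S(5,0)Entropy", "S(0,5)InvDfMom", "S(5,5)AngScMom", "S(5,5)SumEntrp", "Teta3"],
  "groups": ["control", "SPS1d", "SPS4d", "SPS7d", "SPS14d"],
  "intercepts": {
    "control": -2292.719,
    "SPS1d": -2247.184,
    "SPS4d": -2156.604,
    "SPS7d": -2224.278,
    "SPS14d": -2186.556
  },
  "coefficients": {
    "control": {
      "Perc.10%": 0.949,
      "S(1,0)InvDfMom": 824.352,
      "S(0,1)DifEntrp": -135.774,
      "S(1,-1)Entropy": 509.869,
      "S(2,0)InvDfMom": 92.995,
      "S(2,0)SumAverg": 19.055,
      "S(3,0)AngScMom": 12704.031,
      "S(3,3)Correlat": -92.374,
      "S(3,3)DifVarnc": -0.084,
      "S(4,0)Contrast": 1.163,
      "S(4,0)InvDfMom": 255.818,
      "S(4,0)DifVarnc": -1.985,
      "S(0,4)DifEntrp": 54.63,
      "S(4,4)AngScMom": 1433.68,
      "S(4,-4)SumEntrp": 32.173,
      "S(5,0)Correlat": 5.226,
      "S(5,0)Entropy": 647.747,
      "S(0,5)InvDfMom": 430.129,
      "S(5,5)AngScMom": 2611.453,
      "S(5,5)SumEntrp": 254.037,
      "Teta3": 36.736
    },
    "SPS1d": {
      "Perc.10%": 0.829,
      "S(1,0)InvDfMom": 835.211,
      "S(0,1)DifEntrp": -154.71,
      "S(1,-1)Entropy": 473.339,
      "S(2,0)InvDfMom": 67.728,
      "S(2,0)SumAverg": 19.338,
      "S(3,0)AngScMom": 12031.888,
      "S(3,3)Correlat": -80.063,
      "S(3,3)DifVarnc": 0.008,
      "S(4,0)Contrast": 1.153,
      "S(4,0)InvDfMom": 294.17,
      "S(4,0)DifVarnc": -1.984,
      "S(0,4)DifEntrp": 60.536,
      "S(4,4)AngScMom": 1858.346,
      "S(4,-4)SumEntrp": 23.455,
      "S(5,0)Correlat": 4.196,
      "S(5,0)Entropy": 679.793,
      "S(0,5)InvDfMom": 427.754,
      "S(5,5)AngScMom": 2427.192,
      "S(5,5)SumEntrp": 245.623,
      "Teta3": 33.608
    },
    "SPS4d": {
      "Perc.10%": 0.749,
      "S(1,0)InvDfMom": 804.413,
      "S(0,1)DifEntrp": -148.971,
      "S(1,-1)Entropy": 476.936,
      "S(2,0)InvDfMom": 80.657,
      "S(2,0)SumAverg": 19.308,
      "S(3,0)AngScMom": 11934.474,
      "S(3,3)Correlat": -83.126,
      "S(3,3)DifVarnc": -0.014,
      "S(4,0)Contrast": 1.062,
      "S(4,0)InvDfMom": 288.07,
      "S(4,0)DifVarnc": -1.859,
      "S(0,4)DifEntrp": 40.44,
      "S(4,4)AngScMom": 1677.316,
      "S(4,-4)SumEntrp": 32.639,
      "S(5,0)Correlat": -3.429,
      "S(5,0)Entropy": 650.782,
      "S(0,5)InvDfMom": 395.441,
      "S(5,5)AngScMom": 2407.338,
      "S(5,5)SumEntrp": 248.701,
      "Teta3": 35.821
    },
    "SPS7d": {
      "Perc.10%": 0.583,
      "S(1,0)InvDfMom": 781.072,
      "S(0,1)DifEntrp": -126.008,
      "S(1,-1)Entropy": 508.944,
      "S(2,0)InvDfMom": 123.048,
      "S(2,0)SumAverg": 19.835,
      "S(3,0)AngScMom": 12571.383,
      "S(3,3)Correlat": -88.45,
      "S(3,3)DifVarnc": -0.096,
      "S(4,0)Contrast": 1.141,
      "S(4,0)InvDfMom": 270.227,
      "S(4,0)DifVarnc": -1.872,
      "S(0,4)DifEntrp": 46.123,
      "S(4,4)AngScMom": 1338.626,
      "S(4,-4)SumEntrp": 25.774,
      "S(5,0)Correlat": 10.086,
      "S(5,0)Entropy": 639.1,
      "S(0,5)InvDfMom": 404.116,
      "S(5,5)AngScMom": 2592.253,
      "S(5,5)SumEntrp": 245.984,
      "Teta3": 24.784
    },
    "SPS14d": {
      "Perc.10%": 0.716,
      "S(1,0)InvDfMom": 769.323,
      "S(0,1)DifEntrp": -134.1,
      "S(1,-1)Entropy": 485.945,
      "S(2,0)InvDfMom": 84.945,
      "S(2,0)SumAverg": 19.815,
      "S(3,0)AngScMom": 12270.521,
      "S(3,3)Correlat": -82.62,
      "S(3,3)DifVarnc": -0.089,
      "S(4,0)Contrast": 1.122,
      "S(4,0)InvDfMom": 281.944,
      "S(4,0)DifVarnc": -1.861,
      "S(0,4)DifEntrp": 73.707,
      "S(4,4)AngScMom": 1540.184,
      "S(4,-4)SumEntrp": 11.549,
      "S(5,0)Correlat": 2.981,
      "S(5,0)Entropy": 638.312,
      "S(0,5)InvDfMom": 417.143,
      "S(5,5)AngScMom": 2475.405,
      "S(5,5)SumEntrp": 234.816,
      "Teta3": 31.604
    }
  },
  "priors": {
    "control": 0.2,
    "SPS1d": 0.2,
    "SPS4d": 0.2,
    "SPS7d": 0.2,
    "SPS14d": 0.2
  }
}
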