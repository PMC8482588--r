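{
  "version": "1.0",
  "seed": 20210930,
  "n_draws": 1000000,
  "z_star": 7.4193872521569,
  "thresholds": {
    "X7": 129,
    "X8": 166781,
    "X9": 133420,
    "X10": 129,
    "X11": 390.627687654595,
    "X12": 183.037971541279,
    "X13": 130.4,
    "X14": 129,
    "X15": 129
  },
  "sd": {
    "X7": 10.0030049215019,
    "X8": 215.668390953301,
    "X9": 172.02265774894,
    "X10": 10.002068150586,
    "X11": 9.05456491758529,
    "X12": 2.70317102883753,
    "X13": 8.12175715678363,
    "X14": 10.0026677113058,
    "X15": 10.0070571122921
  },
  "sextile_lo": {
    "X7": 45,
    "X8": 17,
    "X9": 10,
    "X10": 45
  },
  "sextile_hi": {
    "X7": 64,
    "X8": 242,
    "X9": 190,
    "X10": 64
  }
}
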