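{
  "intercept": 2.7200000000000002,
  "coefficients": {
    "RBN": -0.56699999999999995,
    "MAXDP": -4.6609999999999996,
    "Psi_i_0": 0.64200000000000002,
    "SpMax4_Bh(e)": 0.54400000000000004,
    "Mor24u": -2.056,
    "Mor16m": -23.689
  },
  "mixing_rule": "norm_cont",
  "target": "lfl",
  "stats": {
    "r2": 0.96399999999999997,
    "s": 0.13800000000000001,
    "F": 606.44000000000005,
    "n": 145,
    "q": 6
  },
  "provenance": {
    "version": "1.0",
    "descriptor_source": "native pipeline, embedding seed 1"
  }
}
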