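{
  "perfect": {
    "inputs": {"TP": 50, "TN": 50, "FP": 0, "FN": 0},
    "expected": {"mcc": 1.0, "balanced_accuracy": 1.0},
    "provenance": "trivial: perfect prediction"
  },
  "anti_perfect": {
    "inputs": {"TP": 0, "TN": 0, "FP": 50, "FN": 50},
    "expected": {"mcc": -1.0, "balanced_accuracy": 0.0},
    "provenance": "trivial: perfect anti-prediction"
  },
  "mixed": {
    "inputs": {"TP": 30, "FP": 10, "TN": 40, "FN": 20},
    "expected": {"mcc": 0.408248290463863, "balanced_accuracy": 0.7},
    "provenance": "derived: direct evaluation of the MCC formula, (30*40 - 10*20)/sqrt(40*50*50*60)"
  },
  "degenerate_no_positives_predicted": {
    "inputs": {"TP": 0, "TN": 50, "FP": 0, "FN": 50},
    "expected": {"mcc": 0.0, "balanced_accuracy": 0.5},
    "provenance": "trivial: zero-denominator convention returns 0"
  }
}
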