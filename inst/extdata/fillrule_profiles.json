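{
  "fillrule_gaba": {
    "inputs": {"n_pos_eligible": 5085, "n_neg_eligible": 30000, "n_per_class": 10000},
    "expected": {"n_pos": 5085, "n_neg": 14915, "total": 20000},
    "provenance": "reported federated-set composition (GABA-A, MLP labels); negatives fill the positive shortfall"
  },
  "fillrule_cox2_mlp": {
    "inputs": {"n_pos_eligible": 9465, "n_neg_eligible": 30000, "n_per_class": 10000},
    "expected": {"n_pos": 9465, "n_neg": 10535, "total": 20000},
    "provenance": "reported federated-set composition (COX2, MLP labels)"
  },
  "fillrule_cox2_sohn": {
    "inputs": {"n_pos_eligible": 7767, "n_neg_eligible": 30000, "n_per_class": 10000},
    "expected": {"n_pos": 7767, "n_neg": 12233, "total": 20000},
    "provenance": "reported federated-set composition (COX2, SOHN labels)"
  }
}
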