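{
  "name": "fluidsim-physchem-v1",
  "comment": "Frozen 1D/2D physicochemical descriptor block. The descriptor count is configuration-defined, not hard-coded: featurize() asserts the computed block matches this list. 'ob' descriptors come from the OpenBabel property engine (ChemmineOB::propOB); 'graph' descriptors are computed from the heavy-atom graph.",
  "descriptors": [
    {"name": "HBA1",             "source": "ob"},
    {"name": "HBA2",             "source": "ob"},
    {"name": "HBD",              "source": "ob"},
    {"name": "logP",             "source": "ob"},
    {"name": "MR",               "source": "ob"},
    {"name": "MW",               "source": "ob"},
    {"name": "nF",               "source": "ob"},
    {"name": "TPSA",             "source": "ob"},
    {"name": "n_heavy_atoms",    "source": "graph"},
    {"name": "n_carbon",         "source": "graph"},
    {"name": "n_nitrogen",       "source": "graph"},
    {"name": "n_oxygen",         "source": "graph"},
    {"name": "n_sulfur",         "source": "graph"},
    {"name": "n_halogen",        "source": "graph"},
    {"name": "n_rings",          "source": "graph"},
    {"name": "n_aromatic_rings", "source": "graph"},
    {"name": "n_bonds",          "source": "graph"},
    {"name": "n_double_bonds",   "source": "graph"},
    {"name": "n_triple_bonds",   "source": "graph"},
    {"name": "frac_heteroatoms", "source": "graph"}
  ]
}
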