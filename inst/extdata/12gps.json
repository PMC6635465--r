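{
  "pairs": [
    {"gene_a": "CRAMP1L", "gene_b": "BAIAP2",  "risk_orientation": "A_lt_B", "beta": 1.21, "c_index": 0.68},
    {"gene_a": "TALDO1",  "gene_b": "EMP1",    "risk_orientation": "A_lt_B", "beta": 1.40, "c_index": 0.65},
    {"gene_a": "ALG3",    "gene_b": "TSPAN7",  "risk_orientation": "A_lt_B", "beta": 1.22, "c_index": 0.64},
    {"gene_a": "ANGEL2",  "gene_b": "DDX10",   "risk_orientation": "A_lt_B", "beta": 1.31, "c_index": 0.64},
    {"gene_a": "PSMG1",   "gene_b": "SLC7A11", "risk_orientation": "A_lt_B", "beta": 2.38, "c_index": 0.61},
    {"gene_a": "CRAMP1L", "gene_b": "DDX10",   "risk_orientation": "A_lt_B", "beta": 2.07, "c_index": 0.59},
    {"gene_a": "PRPF4B",  "gene_b": "UTP6",    "risk_orientation": "A_lt_B", "beta": 1.78, "c_index": 0.58},
    {"gene_a": "TIA1",    "gene_b": "PSMD11",  "risk_orientation": "A_lt_B", "beta": 1.28, "c_index": 0.57},
    {"gene_a": "ALYREF",  "gene_b": "ALG3",    "risk_orientation": "A_lt_B", "beta": 1.18, "c_index": 0.54},
    {"gene_a": "PDPK1",   "gene_b": "ANGPT1",  "risk_orientation": "A_lt_B", "beta": 1.30, "c_index": 0.54},
    {"gene_a": "PSD4",    "gene_b": "POPDC3",  "risk_orientation": "A_lt_B", "beta": 1.67, "c_index": 0.53},
    {"gene_a": "KMT2B",   "gene_b": "PSMG1",   "risk_orientation": "A_lt_B", "beta": 1.97, "c_index": 0.53}
  ],
  "vote_threshold_high": 6,
  "vote_threshold_highest": 9,
  "meta": {"name": "12-GPS", "endpoint": "OS", "cohort": "bladder carcinoma, stage I-III, surgery only"}
}
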