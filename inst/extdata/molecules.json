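[
  {"comp_id": "ETH", "atoms": [{"element": "C"}, {"element": "C"}],
   "bonds": [[1, 2, 1]]},
  {"comp_id": "EOH", "atoms": [{"element": "C"}, {"element": "C"}, {"element": "O"}],
   "bonds": [[1, 2, 1], [2, 3, 1]]},
  {"comp_id": "EDO", "atoms": [{"element": "C"}, {"element": "C"}, {"element": "O"}, {"element": "O"}],
   "bonds": [[1, 2, 1], [1, 3, 1], [2, 4, 1]]},
  {"comp_id": "GOL", "atoms": [{"element": "C"}, {"element": "C"}, {"element": "C"}, {"element": "O"}, {"element": "O"}, {"element": "O"}],
   "bonds": [[1, 2, 1], [2, 3, 1], [1, 4, 1], [2, 5, 1], [3, 6, 1]]},
  {"comp_id": "ACT", "atoms": [{"element": "C"}, {"element": "C"}, {"element": "O"}, {"element": "O"}],
   "bonds": [[1, 2, 1], [2, 3, 2], [2, 4, 1]]},
  {"comp_id": "PYR", "atoms": [{"element": "C"}, {"element": "C"}, {"element": "O"}, {"element": "C"}, {"element": "O"}, {"element": "O"}],
   "bonds": [[1, 2, 1], [2, 3, 2], [2, 4, 1], [4, 5, 2], [4, 6, 1]]},
  {"comp_id": "LAC", "atoms": [{"element": "C"}, {"element": "C"}, {"element": "O"}, {"element": "C"}, {"element": "O"}, {"element": "O"}],
   "bonds": [[1, 2, 1], [2, 3, 1], [2, 4, 1], [4, 5, 2], [4, 6, 1]]},
  {"comp_id": "BNZ", "atoms": [{"element": "C"}, {"element": "C"}, {"element": "C"}, {"element": "C"}, {"element": "C"}, {"element": "C"}],
   "bonds": [[1, 2, 1], [2, 3, 1], [3, 4, 1], [4, 5, 1], [5, 6, 1], [6, 1, 1]]},
  {"comp_id": "SO4", "atoms": [{"element": "S"}, {"element": "O"}, {"element": "O"}, {"element": "O"}, {"element": "O"}],
   "bonds": [[1, 2, 1], [1, 3, 1], [1, 4, 2], [1, 5, 2]]},
  {"comp_id": "PO4", "atoms": [{"element": "P"}, {"element": "O"}, {"element": "O"}, {"element": "O"}, {"element": "O"}],
   "bonds": [[1, 2, 1], [1, 3, 1], [1, 4, 1], [1, 5, 2]]},
  {"comp_id": "ZN", "atoms": [{"element": "ZN"}], "bonds": []},
  {"comp_id": "MG", "atoms": [{"element": "MG"}], "bonds": []},
  {"comp_id": "HOH", "atoms": [{"element": "O"}], "bonds": []}
]
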