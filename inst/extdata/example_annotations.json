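[
  {
    "case": "case_0001",
    "side": "left",
    "level": "L3",
    "vertices": [[8.5, 10.0], [7.0, 18.5], [12.5, 24.0], [20.0, 22.5], [23.5, 14.0], [17.0, 8.5]]
  },
  {
    "case": "case_0001",
    "side": "right",
    "level": "L3",
    "vertices": [[8.5, 38.0], [7.0, 46.5], [12.5, 52.0], [20.0, 50.5], [23.5, 42.0], [17.0, 36.5]]
  }
]
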