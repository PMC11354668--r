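[
  {"chain": "A", "start": 1,   "end": 110, "region": "VL"},
  {"chain": "A", "start": 111, "end": 220, "region": "CL"},
  {"chain": "C", "start": 1,   "end": 110, "region": "VL"},
  {"chain": "C", "start": 111, "end": 220, "region": "CL"},
  {"chain": "B", "start": 1,   "end": 120, "region": "VH"},
  {"chain": "B", "start": 121, "end": 241, "region": "CH1"},
  {"chain": "B", "start": 242, "end": 360, "region": "CH2"},
  {"chain": "B", "start": 361, "end": 454, "region": "CH3"},
  {"chain": "B", "start": 455, "end": 475, "region": "hinge"},
  {"chain": "D", "start": 1,   "end": 120, "region": "VH"},
  {"chain": "D", "start": 121, "end": 241, "region": "CH1"},
  {"chain": "D", "start": 242, "end": 360, "region": "CH2"},
  {"chain": "D", "start": 361, "end": 454, "region": "CH3"},
  {"chain": "D", "start": 455, "end": 475, "region": "hinge"}
]
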