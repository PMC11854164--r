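[
  {"name": "pH", "low": 4, "center": 5, "high": 6, "unit": ""},
  {"name": "enzyme_pct", "low": 1.5, "center": 3, "high": 4.5, "unit": "%"},
  {"name": "time_min", "low": 40, "center": 60, "high": 80, "unit": "min"}
]
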