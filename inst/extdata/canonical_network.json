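{
  "routes": [
    {"id": "Local1", "a": 15, "alpha": 0.15, "s": 5, "beta": 4, "accessible_to": ["OD1"]},
    {"id": "Expressway", "a": 5, "alpha": 0.075, "s": 3, "beta": 4, "accessible_to": ["OD1", "OD2"]},
    {"id": "Local2", "a": 15, "alpha": 0.15, "s": 5, "beta": 4, "accessible_to": ["OD2"]}
  ],
  "od_demands": {"OD1": 9, "OD2": 6},
  "od_menu": {"OD1": ["Local1", "Expressway"], "OD2": ["Local2", "Expressway"]}
}
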