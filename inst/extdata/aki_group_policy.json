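{
  "groups": {"G1": 0.5, "G2": 0.3, "G3": 0.2},
  "membership": {
    "E01": "G1",
    "E02": "G2", "E03": "G2", "E04": "G2", "E05": "G2", "E06": "G2",
    "E07": "G3", "E08": "G3", "E09": "G3", "E10": "G3"
  }
}
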