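{
  "chains": ["A", "B", "C", "D", "E", "F"],
  "domains": [
    {"id": "D1", "residue_offset": 0},
    {"id": "D2", "residue_offset": 250}
  ],
  "sensor_loop_span": [348, 360],
  "nucleotide": {"resid": 401, "resname": "ADP"},
  "mg": {"resid": 404},
  "pi": {"resid": 402}
}
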