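{
  "model": "glucose",
  "glucose": {"A1": 1.5, "phi": 15}
}
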