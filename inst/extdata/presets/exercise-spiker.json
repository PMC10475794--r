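{
  "model": "combined",
  "glucose": {},
  "C5": [-0.8, 0.7, 0.1],
  "bout_rate_per_day": 1.5,
  "bout_height": 3
}
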