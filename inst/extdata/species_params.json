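{
  "salema": {
    "a": 190.2,
    "b": 0.067,
    "omega": 1.4,
    "delta": 6931.1,
    "t_m": 32.8,
    "t_act": 24.3
  },
  "spinefoot": {
    "a": 176.7,
    "b": 0.050,
    "omega": 1.3,
    "delta": 6762.2,
    "t_m": 42.7,
    "t_act": 32.2
  }
}
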