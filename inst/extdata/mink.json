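{
  "r": 1.2,
  "s": 0.2,
  "K": 100,
  "c": 0.05,
  "n": 3,
  "b": 0.01,
  "d": 0.1,
  "p": 0.05,
  "q": 0.05
}
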