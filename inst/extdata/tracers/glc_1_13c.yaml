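# 100% [1-13C] glucose
natural_13c: false
substrates:
  GLCX:
    - {pattern: "100000", fraction: 1.0}
  CO2X:
    - {pattern: "0", fraction: 1.0}
  FORX:
    - {pattern: "0", fraction: 1.0}
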