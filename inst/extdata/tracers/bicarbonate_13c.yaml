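# 20 mM 13C-bicarbonate + unlabeled glucose
natural_13c: false
substrates:
  GLCX:
    - {pattern: "000000", fraction: 1.0}
  CO2X:
    - {pattern: "1", fraction: 1.0}
  FORX:
    - {pattern: "0", fraction: 1.0}
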