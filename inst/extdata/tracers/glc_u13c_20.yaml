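# 20% [U-13C6] glucose + 80% unlabeled glucose (5.56 mM / 22.22 mM),
# medium CO2 and formate unlabeled. Unlabeled species idealized (no
# natural 13C) by default.
natural_13c: false
substrates:
  GLCX:
    - {pattern: "111111", fraction: 0.2}
    - {pattern: "000000", fraction: 0.8}
  CO2X:
    - {pattern: "0", fraction: 1.0}
  FORX:
    - {pattern: "0", fraction: 1.0}
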