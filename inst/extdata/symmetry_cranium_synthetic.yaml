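# Synthetic 39-landmark cranial symmetry scheme (1-based indices).
# Carries the conventional counts and pairing structure used by the
# simulator and examples; it is NOT a real anatomical landmark definition.
# Edit to match your own digitization protocol.
midline: [1, 2, 3, 4, 5, 6, 7, 8, 9]
paired:
  - [10, 25]
  - [11, 26]
  - [12, 27]
  - [13, 28]
  - [14, 29]
  - [15, 30]
  - [16, 31]
  - [17, 32]
  - [18, 33]
  - [19, 34]
  - [20, 35]
  - [21, 36]
  - [22, 37]
  - [23, 38]
  - [24, 39]
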