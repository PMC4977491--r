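# Synthetic 33-landmark mandibular symmetry scheme (1-based indices).
# Structure only, not real anatomy; edit to match your protocol.
midline: [1, 2, 3, 4, 5]
paired:
  - [6, 20]
  - [7, 21]
  - [8, 22]
  - [9, 23]
  - [10, 24]
  - [11, 25]
  - [12, 26]
  - [13, 27]
  - [14, 28]
  - [15, 29]
  - [16, 30]
  - [17, 31]
  - [18, 32]
  - [19, 33]
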