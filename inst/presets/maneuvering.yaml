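# single target alternating straight legs and coordinated turns; the IMM-PF
# mode-switching scenario
scenario:
  type: maneuvering
  n_targets: 1
  n_frames: 100
  speed_range: [1.2, 1.2]
  turn_rate: 0.6
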