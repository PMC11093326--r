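# well-separated parallel movers, corruption off: tracker must match gt exactly
scenario:
  type: separated
  n_targets: 4
  n_frames: 60
  pos_jitter: 0
  att_jitter: 0
  center_noise: 0
  size_noise: 0
  p_miss: 0
  fp_rate: 0
  occ_iou: 1
  score_true: null
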