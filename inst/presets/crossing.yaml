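# two-target scripted overtake with an exact occlusion gap (frames); the
# occlusion-recovery scenario. Fully deterministic.
scenario:
  type: crossing
  n_targets: 2
  n_frames: 70
  gap: 5
  pos_jitter: 0
  att_jitter: 0
  center_noise: 0
  size_noise: 0
  p_miss: 0
  fp_rate: 0
  occ_iou: 0.5
  score_true: null
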