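# High-effect-size recovery fixture: planted selective neurons must be
# recoverable by SI thresholding + cross-dataset overlap, and their lesion
# must hurt the readout more than every random control.
stimulus:
  size: 32
  images_per_category: 60
  effect_size: 3.0
  noise: 1.0
  thresholds: [4.3, 6.0]
  half_width: 0.0
backbone:
  filters: [16, 16, 32]
  input_size: 32
planted:
  layer: 1
  pleasant: [0, 1, 2, 3]
  neutral: [4, 5, 6, 7]
  unpleasant: [8, 9, 10, 11]
  strength: 3.0
selection:
  keep_fraction: 0.8
controls:
  R: 20
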