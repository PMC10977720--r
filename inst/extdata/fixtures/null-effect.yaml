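# Null-calibration fixture: no category-linked signal (effect size 0);
# genuine-set sizes should match chance and manipulation effects center at 0.
stimulus:
  size: 32
  images_per_category: 45
  effect_size: 0.0
  noise: 1.0
  thresholds: [4.3, 6.0]
  half_width: 0.0
backbone:
  filters: [16, 16, 32]
  input_size: 32
selection:
  keep_fraction: 0.8
seeds: 10
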