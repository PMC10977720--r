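# Toy object-recognition pre-training fixture for the trained-vs-random
# contrast: textured-shape classes share the feature family that links the
# affective categories to their texture statistics.
object:
  n_classes: 4
  images_per_class: 60
  size: 32
  epochs: 6
  lr: 0.05
  batch_size: 32
affective:
  size: 32
  images_per_category: 45
  effect_size: 0.7
  noise: 3.0
selection:
  keep_fraction: 0.8
seeds: 5
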