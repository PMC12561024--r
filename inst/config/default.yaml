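# Default run configuration. Every method constant appears here;
# values omitted in a user config fall back to these.
phantom:
  height_px: 192
  width_px: 192
  pixel_spacing_mm: 0.2
  bone_brightness: 0.9
  bone_thickness_px: 1.8
  shadow_attenuation: 0.25
  speckle_scale: 0.4
  n_distractor_lines: 2
  gain_range: [0.75, 1.15]
  empty_fraction: 0.0777  # 363 / 4672
augment:
  blur_sigma: 5.0
  rotation_deg: [-10, 10]
  shear_factor: [-0.2, 0.2]
  contrast_range: [0.25, 1.75]
  augment_fraction: 0.25
  op_prob: 0.5
model:
  in_channels: 1
  conv_channels: [16, 32, 128]
  embed_dims: [160, 256]
  out_channels: 1
  input_size: [192, 192]
schedule:
  warmup_epochs: 10
  pos_weight: 20.0
  final_cl_weight: 0.5
  ramp: linear
train:
  total_epochs: 60
  batch_size: 8
  lr: 0.001
  weight_decay: 0.0005
  scheduler_factor: 0.5
  scheduler_patience: 3
  n_folds: 5
  combine: uniform
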