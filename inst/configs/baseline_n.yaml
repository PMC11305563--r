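depth_multiple: 0.3333333
width_multiple: 0.25
max_channels: 1024
num_keypoints: 16
keypoint_dims: 3
num_classes: 1
reg_max: 16
simam_stages: []
simam_omega: 0.0001
neck: pan_baseline
repblock_depths:
- 1
- 1
- 1
- 1
neck_widths:
  w4: 48
  w3: 32
  d3: 64
  d4: 160
  p3: 48
  p4: 128
  p5: 256
input_size: 640
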