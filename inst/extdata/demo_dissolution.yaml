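# Demo run: simulate a sigmoid dissolution movie and quantify it end to end.
seed: 42
simulate:
  image_shape: [96, 96]
  n_frames: 100
  frame_interval_s: 3
  n_droplets: 6
  droplet_radius_px: [3, 5]
  dilute_level: 50
  partition_coefficient: 6
  background_level: 10
  kinetics_model: sigmoid_decay
  tau_s: 30
  onset_s: 60
segment:
  condensate_method: otsu
  cell_method: mean
  min_object_px: 4
  reference_frame: 1
quantify:
  background: auto
kinetics:
  model: sigmoid
  onset_s: 60
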