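# Minimal end-to-end configuration: generate a small phantom cohort, train
# a depth-8 RL-gated classifier for a few epochs, evaluate and explain.
#   drlroi generate --config smoke.yaml --out run
#   drlroi train    --config smoke.yaml --out run
#   drlroi evaluate --config smoke.yaml --out run
seed: 1
output_dir: drlroi_smoke
phantom:
  n_patients_per_class: 8
  slices_per_patient: 2
  image_size: 32
  roi_radius_range: [5.0, 8.0]
  background_distractor_count: 6
  noise_sigma: 0.1
  roi_center_jitter: 0.08
backbone:
  stem_channels: 4
  stage_channels: [4, 8, 16]
  blocks_per_stage: 1
  input_size: 32
rl:
  hidden: [16, 16]
train:
  epochs: 5
  batch_size: 8
eval:
  n_val_per_class: 2
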