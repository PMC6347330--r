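# Bundled demonstration configuration: a reduced version of the default
# pipeline that completes in well under a minute on one CPU.
seed: 1
out_dir: deeprecon_demo
stimuli:
  n_train: 120
  n_test: 20
  size: 12
  test_repeats: 2
extractor:
  filters: [6, 8]
  fc_units: [24, 8]
encoding:
  n_voxels: 250
  nonzeros_per_voxel: 12
  noise_sd_factor: 0.1
runs:
  blocks_per_run: 40
  block_seconds: 8
  tr_seconds: 2
  amplitude_percent_sd: 2
  drift_amplitude: 5
  motion_amplitude: 0.5
  noise_sd: 0.3
decoding:
  layer: conv1_1
  unit_subsample: 320
  voxel_cap: 60
  max_iter: 30
norm_correction:
  n_reference: 60
recon:
  optimizer: lbfgs
  max_iter: 150
  initial_image: mean
verbose: true
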