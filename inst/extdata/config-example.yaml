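# Example configuration overriding a few defaults; pass to load_config()
# or any CLI command via --config.  Unlisted keys keep their defaults.
blocks:
  block_size: 48
  overlap_step: 8
bpnn:
  n_hidden: 4
  error_goal: 0.0005
graphcut:
  lambda_grid: [5]
phantom:
  noise_sd: 0.08
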