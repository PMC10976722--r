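# Example configuration for `evaluesim run --config` / read_config().
# Omitted fields fall back to the calibrated defaults; unknown fields error.
n_replicates: 50
master_seed: 2024
rho_grid: [0.0, 0.3, 0.6, 0.9]
calipers: [0.001, 0.01]
s_dist:
  family: uniform
  min: 1.95
  max: 2.45
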