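# Example run configuration: the method's default operating point with a
# noisy femoral-head study. Load with load_config().
algorithm:
  p: 0.5
  mu: 1.0
  d_max: 5.0
  k_max: 100
  k_neighbors: 30
phantom:
  shape: ball_shaft
  n_probe: 30
  probe_noise_sigma: 0.2
  outlier_fraction: 0.2
seed: 1
log_level: info
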