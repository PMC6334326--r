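# Default pipeline configuration: the nominal validated CE assay conditions.
simulation:
  calibration_levels: [70, 80, 90, 100, 110, 120]
  replicates: 3
  response_slope: 2281.7
  response_intercept: -24495
  noise_sd: 1000
  migration_time: 3.2
  migration_jitter_sd: 0.02
  peak_sigma: 0.031
  sampling_rate: 600
  run_length: 5
  baseline_drift_slope: 0.1
  baseline_noise_sd: 0.05
  seed: 1
rsd_limit: 2
alpha: 0.05
sst_n: 10
repeatability_n: 7
precision_days: 3
recovery_added: [10, 30, 50]
recovery_base: 70
factor_effects: [0, 0, 0, 0, 0, 0, 0]
robustness_noise_sd: 0.3
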