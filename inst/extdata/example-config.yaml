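# Example pipeline configuration (see load_run_config()).
out_dir: bcrsyk_output
scenario: AQL
seed: 7
protocol:
  doses: [5.5, 16.5, 50.0, 150.0]
  t_obs_erkp: 5
  t_obs_ikb: 15
synthetic:
  shape: healy_like
  noise: linear_sigma
screening:
  param_names: [rw0_kf, rw9_kf, r18_kf]
  n_candidates: 50
contour:
  n_per_axis: 5
  oi_dose: 1
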