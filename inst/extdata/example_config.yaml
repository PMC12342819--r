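# Example iricrest run configuration. Unset keys fall back to the shipped
# defaults (see default_run_config()); unknown keys are rejected.
seed: 1
output_dir: iricrest_run
stages:
  synthetic: true
  sweep: true
  taphonomy: true
lattice:
  # measured melanosome means (nm) and the shipped packing defaults;
  # "y" is quoted because bare y/n are YAML 1.1 booleans
  x: 186
  "y": 283
  z: 1774
  tilt_deg: 20
  shear_s: 0.35
  n_layers: 10
  cortex_t: 100
incidence:
  plane: XY
  theta_list: [0, 20, 40, 50, 60, 70]
  polarization: sp
  lambda_min: 400
  lambda_max: 800
  lambda_step: 5
solver:
  name: tmm          # fdtd for the full 2D lattice solver
  delta: 5
taphonomy:
  scale_factor: 1.10
  gap_jitter_sd: 10
  n_realizations: 5
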