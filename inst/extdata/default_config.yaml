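schema_version: 1
kernel: resource_dependent
seed: 1
params:
  alpha: 0.1
  beta: 0.1
  K: 0.1
  E_total: 1.0
  K_M: 1.0
  delta_m: 0.0
  delta_p: 0.0
schedule:
  replaced_fraction: 0.2
  cycle_interval: 15.0
segments:
- 0.2
- 0.12
- 0.04
protocol:
  t_switch:
  - 240.0
  - 960.0
  t_end: 1200.0
feeds:
  d_G: 1.0
  p_T: 1.0
  R: 1.0
titration:
  low: 0.005
  medium: 0.1
  high: 2.0
analysis:
  sr_pc_time: 900.0
  threshold_fraction: 0.1
  washout_margin: 0.05
noise:
  relative_sd: 0.02
  background_offset: 0.0
  background_drift: 0.0
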