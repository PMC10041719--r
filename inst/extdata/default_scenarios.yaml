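sweep:
  severities:
  - 0.3
  - 0.4
  - 0.5
  - 0.6
  - 0.7
  - 0.8
geometry:
  inlet_radius: 0.0015
  vessel_length: 0.03
  stenosis_center: 0.015
  stenosis_length: 0.01
waveform:
  mean_pressure: 9300.0
  pulse_amplitude: 1500.0
  period: 0.8
  systolic_peak_time: 0.4
  n_samples: 101
fluid:
  density: 1060.0
  rheology:
    eta_inf: 0.00345
    eta_0: 0.056
    'n': 0.3568
    lambda: 3.313
solver:
  time_step: 0.00025
  cycles_total: 3
  cycles_discarded: 2
  residual_tolerance: 0.0001
  advection: upwind2
  cfl: 0.35
  grid_nx: 240
  grid_nr: 48
  samples_per_cycle: 100
calibrated_defaults: yes
output:
  vtk: yes
  probe_offset: 0.003
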