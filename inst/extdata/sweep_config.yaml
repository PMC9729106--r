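# example conduction-sweep configuration
diameter_grid: [0.3, 0.5]
area_grid: [0, 500, 7100]
density_grid: [0, 1.1]
protocol: single
sim_duration_ms: 300
channels:
  gNa_max: 0.12
  gK_max: 0.036
  gLeak: 0.0003
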