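arena_side: 100.0
days: 10
replicates: 10
spawn_delay:
  mean: 8.7
  sd: 4.9
  lo: 0.0
  hi: 24.83
mating_metric: cumulative
base_seed: 1
factors:
  densities:
  - 10.0
  - 100.0
  - 1000.0
  speeds: low
  rests: zero
  tracking: no
  pd_max: 0.5
  tau: 0.0
  barriers: none
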