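# Long-run configuration: equilibrium decision-time floor for the
# five-binding-site circuit under strong noncognate interference
# (w/c = 1400). At full budget the equilibrium minimum is ~1100 burst
# cycles; desk-scale runs verify only that equilibrium performance collapses
# once w/c exceeds the affinity factor.
spec:
  n_binding_sites: 5
  n_activation_steps: 1
  include_noncognate: true
  affinity_factor: 100.0
  max_rate: 1.0
conc:
  c: 1.0
  w: 1400.0
  delta_c_rel: 0.1
sweep:
  metric: IR_nats
  n_init: 200000
  n_generations: 20000
  n_mutants: 30
  n_elite: 8
  mutation_scale: [0.6, 0.02]
  seed: 314159
  log_bounds: [-5.0, 5.0]
  equilibrium_only: true
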