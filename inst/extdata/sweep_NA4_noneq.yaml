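# Long-run configuration: nonequilibrium information-rate boundary for the
# one-binding-site circuit with four activation steps. At full budget this
# traces the high-dissipation regime where decisions take ~8 burst cycles at
# >= 180 kT per burst; desk-scale runs reproduce the direction but not the
# tight endpoint.
spec:
  n_binding_sites: 1
  n_activation_steps: 4
  include_noncognate: false
  affinity_factor: 100.0
  max_rate: 1.0
conc:
  c: 1.0
  w: 0.0
  delta_c_rel: 0.1
sweep:
  metric: IR_nats
  n_init: 200000
  n_generations: 20000
  n_mutants: 30
  n_elite: 8
  mutation_scale: [0.6, 0.02]
  seed: 271828
  log_bounds: [-5.0, 5.0]
  equilibrium_only: false
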