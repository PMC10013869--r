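# burstinfo

Energy dissipation and information transmission in bursty gene circuits.

## The problem

Eukaryotic transcription happens in stochastic bursts: a gene locus
fluctuates between an inactive (OFF) conformation and an active (ON)
conformation that produces mRNA at rate *r₀*. A cell reading that noisy
output must decide — within a limited number of burst cycles — whether the
concentration of a cognate transcriptional activator is high (*c₁*) or low
(*c₀*). Several steps of the transcriptional cycle hydrolyze ATP, so the
underlying molecular network need not obey detailed balance. `burstinfo`
asks, quantitatively: **what does that energy buy?**

The package is aimed at quantitative/systems biologists who want to
reproduce, probe or extend this analysis: it builds the kinetic models,
computes every performance metric analytically, sweeps parameter space for
achievable-region boundaries, and validates everything against exact
stochastic simulation.

## The model and metrics

A gene locus with `N_B` identical activator binding sites and `N_A`
molecular activation steps is a continuous-time Markov chain on states
`(n_c, n_w, m)` — the number of cognate- and noncognate-bound sites and the
number of engaged activation steps; the locus transcribes only when
`m = N_A`. Four basal rates (binding `k_b·c`, unbinding `k_u`, activation
`k_a`, deactivation `k_i`) are modulated by dimensionless interaction
factors `η`: each bound activator multiplies activation by `η_ab` and
deactivation by `η_ib`; each engaged activation component multiplies
unbinding by `η_ua` and binding by `η_ba`; `η_ub` encodes pairwise
activator cooperativity. Noncognate activators (aggregate concentration
`w`) are identical except they unbind `α = 100` times faster.

For the minimal four-state circuit (one site, one step) the distance from
equilibrium is the cycle affinity `ln(η_ab η_ua / (η_ib η_ba))`, and the
dissipation rate is

    Φ = J · ln(η_ab η_ua / (η_ib η_ba))        [kT per unit time]

with `J` the net cycle flux; in general Φ is the Schnakenberg entropy
production `Σ_{i<j} (π_i k_ij − π_j k_ji) ln(π_i k_ij / π_j k_ji)`. All
quantities are reported per **burst cycle** `τ_b`, the mean time for one
ON → OFF → ON fluctuation.

From the stationary distribution the package computes analytically:

- **sharpness** `s = c* ∂π_a/∂c` and its normalized (Hill-coefficient-like)
  form `S = s/(π_a(1−π_a))`;
- **precision** `p = (2v)^{−1/2}` from the asymptotic variance rate `v` of
  the ON indicator (burst units), normalized as `P = p·π_a(1−π_a)`;
- **specificity** `f = (w/c)·π_c/π_w` and the cognate binding fraction
  `p_c = f/(f + w/c)`;
- the **information rate** `IR = (δc/c*)² s² p²` (nats/burst, reported in
  bits) and the sequential-test **decision time**
  `T̄ = (1−2ε)·ln((1−ε)/ε)/IR`.

At equilibrium these obey hard limits — `S ≤ N_B`, `P ≤ 1/2`, `f = α` — and
the central results the package reproduces are how dissipation breaks them:
`S` up to `N_A + 1`, `f` up to `α^{N_A+1}`, a fourfold information-rate
gain for the four-state circuit (0.0035 → 0.014 bits/burst, reached near
Φ ≈ 20 kT/burst), and the observed-sharpness ceiling
`S ≤ f/(w/c + f) · S₀` under noncognate interference.

## Worked example

```r
library(burstinfo)

p <- rate_params(k_b = 2, k_u = 1, k_a = 1, k_i = 0.5,
                 eta_ab = 8, eta_ib = 0.1, eta_ua = 5, eta_ba = 0.4)
m <- build_rate_matrix(circuit_spec(), p, concentrations())
detailed_balance_residual(m)
#> [1] 6.907755
response_summary(circuit_spec(), p, concentrations())
#> <response_summary>
#>    pi_a  r_bar tau_b phi_rate phi_per_burst       s       v     p      S      P
#>  0.8466 0.8466 2.828    1.527         4.318 0.07774 0.02876 4.169 0.5986 0.5415
#>   IR_nats  IR_bits T_bar
#>  0.001051 0.001516 258.3
```

This circuit has cycle affinity `ln(8·5/(0.1·0.4)) ≈ 6.91`, dissipates
4.3 kT per burst cycle, and spends it on precision (`P = 0.54` exceeds the
equilibrium barrier of 1/2) rather than sharpness: at `S·P ≈ 0.32` it
transmits 0.0015 bits per burst, so it would need ~258 burst cycles to
distinguish a 10% concentration difference at one-sigma error — an
*inefficient* use of energy. Asking the sweep engine for the best possible
circuit instead:

```r
best <- maximize_metric(circuit_spec(), "IR_nats",
                        sweep_config(seed = 1))
best$metrics$IR_bits      # ~0.0143 bits/burst (S ~ 2, P ~ 1/2)
decision_time(best$value) # ~27 bursts
```

The same engine traces full boundaries
(`pareto_boundary(spec, "phi_per_burst", "IR_bits", ...)`), scans
noncognate interference (`scan_vs_wc()`), and reproduces the binding-site
mutation signatures (`perturbation_response()`,
`equilibrium_response_region()`). `gillespie()`, `estimate_metrics()` and
`sprt_decision_times()` provide the exact-simulation counterparts of every
analytic quantity.

## Package layout

| File | Contents |
| --- | --- |
| `R/circuit_models.R` | state enumeration, generator assembly, detailed-balance machinery |
| `R/steady_state.R` | stationary solve, entropy production, burst cycle time |
| `R/response_metrics.R` | sharpness, precision, specificity, envelope |
| `R/information.R` | information rate, decision-time bound |
| `R/sweep.R` | evolutionary boundary tracing and metric maximization |
| `R/stochastic_sim.R` | Gillespie simulation, empirical estimators, SPRT, fixtures |
| `R/perturbation.R` | binding-site mutation signatures |
| `R/io.R` | YAML/JSON/CSV/GraphML serialization |

The methods vignette (`vignettes/nonequilibrium-gene-circuits.Rmd`)
documents the modeling conventions, numerical choices and limitations.
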