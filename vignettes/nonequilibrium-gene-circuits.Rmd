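---
title: "Nonequilibrium gene circuits: models, metrics and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonequilibrium gene circuits: models, metrics and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstinfo)
```

This vignette is the package's own account of the science it implements:
the kinetic model and its assumptions, the conventions behind each metric,
the design choices made where several reasonable options existed, and what
the test suite does and does not establish about real transcription.

## The model

A gene locus is a continuous-time Markov chain over states $(n_c, n_w, m)$:
$n_c$ cognate-bound and $n_w$ noncognate-bound sites out of $N_B$ identical
activator binding sites, and $m$ of $N_A$ molecular activation steps
engaged. mRNA is produced, at rate $r_0$, only while every activation
component is engaged ($m = N_A$); a *burst cycle* is one
ON $\to$ OFF $\to$ ON fluctuation of that conformation. The chain mixes
fast compared with decision timescales, so all quantities are computed at
stationarity.

Transitions follow exponent-counting rate laws. With $n = n_c + n_w$ bound
sites:

| transition | rate |
| --- | --- |
| cognate binding | $(N_B - n)\, k_b\, c\, \eta_{ba}^{\,m}$ |
| cognate unbinding | $n_c\, k_u\, \eta_{ua}^{\,m}\, \eta_{ub}^{\,n-1}$ |
| noncognate binding | $(N_B - n)\, k_b\, w\, \eta_{ba}^{\,m}$ |
| noncognate unbinding | $n_w\, \alpha\, k_u\, \eta_{ua}^{\,m}\, \eta_{ub}^{\,n-1}$ |
| activation $m \to m+1$ | $(N_A - m)\, k_a\, \eta_{ab}^{\,n}$ |
| deactivation $m \to m-1$ | $m\, k_i\, \eta_{ib}^{\,n}$ |

Each molecule of one component present multiplies the other component's
transitions by one interaction factor. For $N_B = N_A = 1$ this is exactly
the canonical four-state (or, with the noncognate competitor, six-state)
circuit. We considered the alternative of applying $\eta_{ua}/\eta_{ba}$
only in the fully active conformation; it agrees for $N_A = 1$ but caps the
achievable normalized sharpness at 2 for every $N_A$, whereas the
exponent-counting law reproduces the expected linear scaling
$S_{neq} \le N_A + 1$ (measured: 2.98 at $N_A = 2$) and the exponential
proofreading capacity of deeper activation ladders. It also gives every
elementary square cycle of the occupancy–conformation lattice the same
affinity, $\ln(\eta_{ab}\eta_{ua}/(\eta_{ib}\eta_{ba}))$, so a single
substitution $\eta_{ba} := \eta_{ab}\eta_{ua}/\eta_{ib}$ places any
parameter set on the detailed-balance manifold for all $N_B, N_A$.

Noncognate activators are kinetically identical to cognate ones except for
an $\alpha$-fold faster unbinding; $\alpha = 100$ throughout, reflecting
the free-energy difference of a few $k_BT$ between specific and nonspecific
binding of eukaryotic transcription factors. Concentrations are in units of
the midpoint $c^*$, so the operating point is $c = 1$, and the two
hypothesis concentrations differ by $\delta c/c^* = 0.1$.

## Metrics and conventions

**Stationary solve.** $\pi^T Q = 0$ with normalization, via a bordered
dense solve with one step of iterative refinement; models never exceed a
few dozen states. Transient states (e.g. noncognate-bound states at
$w = 0$) are removed before any metric is computed.

**Dissipation.** The Schnakenberg entropy production
$\Phi = \sum_{i<j}(\pi_i k_{ij} - \pi_j k_{ji})\ln\frac{\pi_i k_{ij}}{\pi_j k_{ji}}$,
reported per burst cycle ($\Phi \tau_b$, units of $k_BT$). A circuit is
classified as at equilibrium when $\Phi\tau_b < 10^{-8}$.

**Burst cycle time.** $\tau_b$ is the reciprocal of the stationary one-way
OFF $\to$ ON crossing frequency, $1/\sum_{i \in \mathrm{OFF}, j \in
\mathrm{ON}} \pi_i k_{ij}$. For the telegraph (two-state) circuit this
equals the mean cycle time $1/k_{on} + 1/k_{off}$ exactly; we chose the
boundary-flux form over first-passage matrix algebra because it is cheap,
smooth in the rates, and identical for the two-macrostate structure of all
models used here. Trajectory-based cycle counting cross-checks it in the
tests.

**Sharpness.** $s = c^*\,\partial \pi_a/\partial c$ by implicit
differentiation of the stationary condition (a second bordered solve), with
$w$ held fixed; finite differences at $h = 10^{-6}$ agree to $10^{-5}$
relative in the tests. Normalized: $S = s/(\pi_a(1-\pi_a))$, the Hill
coefficient of an equally sharp Hill function.

**Precision.** The asymptotic variance rate of the time-integrated ON
indicator comes from the Poisson equation $Qg = \pi_a \mathbf{1} -
\mathbf{1}_{ON}$, $v_{abs} = 2\sum_i \pi_i(\mathbf{1}_{ON,i}-\pi_a)g_i$.
Time is measured in burst cycles, which rescales the variance rate to
$v = v_{abs}/\tau_b$; precision is $p = (2v)^{-1/2}$ and $P =
p\,\pi_a(1-\pi_a)$. This convention is anchored by three closed forms that
the tests pin down: the telegraph circuit gives $v = 2\pi^2(1-\pi)^2$ and
hence $P = 1/2$ exactly; the equilibrium four-state information optimum is
0.0036 bits/burst; the nonequilibrium optimum is 0.0144 bits/burst.
Synthesis (Poisson) shot noise is excluded from $p$ — locus-switching noise
dominates — though the simulator can add it to accumulated-mRNA traces.

**Information rate and decision time.** For Gaussian output noise the
Kullback–Leibler divergence between the outputs under $c_0$ and $c_1$
accumulates at $IR = (\delta c/c^*)^2 s^2 p^2$ nats per burst (the
occupancy normalizations cancel: $sp = SP$); reported in bits. The
sequential probability ratio test converts it to the decision-time bound
$\bar T = (1-2\varepsilon)\ln\frac{1-\varepsilon}{\varepsilon}/IR$, with
$\varepsilon = 0.32$ ("one sigma") unless stated.

**Specificity.** $f = (w/c)\,\pi_c/\pi_w$ with occupancy-weighted bound
probabilities $\pi_c = \sum_i n_{c,i}\pi_i$ (for one site, the bound-state
probability). The occupancy weighting is the choice for which the
equilibrium pinning $f^{eq} = \alpha$ holds exactly for every $N_B$. At
$w = 0$, $\pi_w$ vanishes linearly in $w$, so $f$ is evaluated at
$w = 10^{-8}$ and flagged as a limit. Intrinsic sharpness $S_0$ is the
normalized sharpness of the same parameters with the noncognate species
removed.

**The sharpness envelope.** $S \le \frac{f}{w/c + f}\,S_0$ bounds the
*achievable region*: swept maxima approach it within 1% (0.903 vs 0.909
nonequilibrium, 0.090907 vs 0.090909 equilibrium, at $w/c = 10^3$). It is
not a per-circuit identity — a circuit whose response to $c$ operates by
displacing noncognate competitors can show finite $S$ with near-zero
$S_0$ — so the tests assert it at the boundary, where it is tight.

## The sweep engine

Boundary tracing uses a binned-archive evolutionary search: log-uniform
initialization inside $10^{-5} \le \eta \le 10^{5}$ (with the activator
constraint $\eta_{ab} \ge 1$, $\eta_{ib} \le 1$ built into the box),
followed by rounds of Gaussian log10-space mutation of archive members with
a geometrically annealed scale and elitist replacement. Because the bound
on rate magnitudes is expressed in burst-time units
($10^{-5} \le k\tau_b \le 10^{5}$) it can only be evaluated after the
stationary solve, so it acts as a post-evaluation filter; the $\eta$ bounds
and the derived $\eta_{ba}$ of equilibrium draws are enforced at proposal
time. Equilibrium sweeps sample directly on the detailed-balance manifold
($\eta_{ba}$ substituted), so every equilibrium circuit has zero cycle
affinity by construction rather than by rejection: we deliberately sample
the $\eta$ family on its equilibrium manifold, rather than generic
energy/barrier landscapes, because it preserves the activator constraint
and the fixed affinity factor $\alpha$ that the specificity results rely
on. The energy/barrier construction (`equilibrium_sample()`) remains the
generator of *arbitrary* equilibrium circuits for the barrier-property
tests, where full generality is the point.

Only the attained boundary is asserted anywhere — never the search path —
and reruns with one seed are bit-identical. Ties keep the earlier
candidate. An infeasible constraint set (e.g. an impossible half-maximum
filter) returns a flagged empty result rather than an error.

Default problem sizes (`sweep_config()`: 5000 initial draws, 200
generations of 24 mutants) converge the four-state optima to within ~1% and
run in seconds; the acceptance script uses 3000/250/24 for the four-state
optima and 6000/400/30 for the nine-state interference model, sizes at
which independent seeds agree to three digits.

## The simulator as oracle

`gillespie()` is an exact stochastic simulation of the chain;
`estimate_metrics()` recovers $\pi_a$, $\tau_b$ and $v$ from trajectories
(batch means with bootstrap errors), and `sprt_decision_times()` runs the
actual sequential test: it accumulates the Gaussian drift-diffusion
log-likelihood ratio of the integrated output along simulated paths and
stops at the Wald thresholds $\pm\ln((1-\varepsilon)/\varepsilon)$. The
log-likelihood ratio is piecewise linear between jumps, so crossings are
located exactly; replicates that reach the duration cap are reported as a
cap-hit fraction. We use the Gaussian approximation rather than the exact
path likelihood deliberately: the decision-time bound being validated is
itself derived under Gaussian output noise, and the empirical mean decision
time matches it within a few percent for circuits with many bursts per
decision (the tests require 15%). Circuits with $\pi_a$ near 0 or 1, or so
informative that decisions take only a few bursts, leave the
drift-diffusion regime and are outside the validated domain.

Synthetic datasets (`make_fixture()`) serialize trajectory ensembles as
CSV plus a JSON sidecar; the default ensemble of 100 trajectories mirrors
the ensembles used for accumulated-mRNA noise bands. What the generator
emulates is the *model's* stochasticity — locus-state switching and
(optionally Poisson) synthesis noise. It does not emulate extrinsic noise,
cell-to-cell parameter variability, mRNA degradation, or measurement
noise, so passing tests establish internal consistency of the analytic
machinery, not agreement with any experimental dataset.

## Perturbation signatures

`perturbation_response()` models binding-site mutations as $k_u \to \beta
k_u$ for the cognate species only ($\beta \ge 1$; noncognate unbinding
keeps $\alpha k_u$, and $\beta = \alpha$ is full loss of cognate
specificity). Default perturbation strengths $\beta \in \{3.16, 10, 100\}$
span half-decade steps up to that conversion. The normalized sharpness fold
is $(S^{mut}/S)\cdot\beta$, reading "normalize by $k_u/k_u^{mut}$" as
division by that ratio. For region comparisons the wild type is required to
sit at half-maximal expression ($|\bar r/r_0 - 1/2| \le 0.01$); the
tolerance is a numerical width for an equality constraint inside a
rejection-based sweep.

## Known limitations

- Sweeps give attained boundaries, not optimality certificates; endpoint
  anchors are the evidence of convergence.
- The $w \to 0$ specificity limit is computed at $w = 10^{-8}$; relative
  error is of the same order.
- Large-horizon results (four activation steps, five-site interference
  floors, the $10^3$-fold gain at $w/c = 10^5$, many-site extrapolations)
  need orders of magnitude more evaluations than the shipped defaults; the
  package ships their configurations (`inst/extdata/*.yaml`) and the tests
  check direction only.
- All analysis assumes stationarity of the locus chain within a decision;
  pre-steady-state transients are out of scope.
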