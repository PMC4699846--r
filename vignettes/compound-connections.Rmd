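---
title: "Compound-connection models of synaptic turnover: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compound-connection models of synaptic turnover: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(synturn)
```

## The model

A compound-connection is the set of all `N` potential synaptic sites
between one presynaptic and one postsynaptic neuron; `S` of them host a
realized synapse. The dynamics are a discrete-time Markov chain on
`S ∈ {0, …, N}`: each vacant site forms a synapse with probability `b` per
step, each occupied site is deleted with probability `d[S]`, which depends
on the current count (this is the abstraction of the positive feedback
between synapse number, postsynaptic activity and synapse stability). In
the one-change-per-step (first-step) approximation the transition matrix
is tridiagonal, with up-rate `(N − S) b`, down-rate `S d[S]`.

Stimulation is abstracted into three conditions, each *defined* by its
stationary distribution: `low` (truncated Poisson, parameter `λ`), `high`
(truncated Gaussian, center `μ`, width `σ` — note the exponent
`−(S − μ)²/σ²`), and the bimodal working point `wp`, the `C`-weighted
mixture of the two. Deletion rates are obtained by inverting the target
through detailed balance,
`d[S] = ((N − S + 1)/S) (p[S−1]/p[S]) b`,
which requires strict positivity of the target — guaranteed by
construction for all three shapes, and deliberately *not* patched by
epsilon-flooring for user-supplied targets: a zero entry is a modelling
error, not a numerical one.

### Parameters and defaults

| parameter | meaning | default | unit |
|---|---|---|---|
| `N` | potential synapses per connection | 7 (5 for calibration/retraining) | sites |
| `b` | formation rate per vacant site | 1e-8 | probability/step |
| `μ`, `σ` | upper-peak center and width | 5, 1.2 (1.0 for retraining) | synapse counts |
| `λ` | lower-peak Poisson parameter | 0.05 | – |
| `C` | upper-peak weight | 0.1 | probability |

`N` is nowhere fixed by first principles; we use the smallest value
compatible with the all-mass-at-seven initial condition of the decay
protocols (`N = 7`) and expose `N` everywhere. The calibration and
spine-turnover (retraining) protocols use `N = 5`, the parameterization
under which the steps-per-day calibration was originally stated, with
`σ = 1.0` for the retraining timeline. All time scales are proportional
to `1/b`; `b = 1e-8` puts one synaptic lifetime at ~10⁸ steps.

## Numerical strategy

**Stationary distributions.** For an irreducible tridiagonal chain the
invariant vector follows the flow-balance recursion
`p[S]/p[S−1] = up(S−1)/down(S)`, evaluated in log space. This is exact;
a generic eigenvector solve would be limited by the spectral gap, which at
`b = 1e-8` is ~6·10⁻¹⁰ and would destroy the `1e-10` round-trip accuracy
the detailed-balance construction is entitled to.

**Propagation.** `p(t) = p(0) Mᵗ` is computed through the symmetrized
decomposition of `M − I` (every chain built here is reversible): eigenvalue
errors then scale with `‖M − I‖ ≈ b` rather than 1, and `(1 + q)ᵗ` is
evaluated as `exp(t·log1p(q))`, so relaxation rates of order 10⁻¹⁰ are
resolved at `t = 10¹²` without error growth. Square-and-multiply matrix
powers remain as a fallback for non-reversible input. Stepwise
multiplication is used only as a test oracle — at 10¹⁰ steps it is not an
option.

**Event-driven simulation.** The stochastic simulator holds one geometric
waiting time per site (inverse-CDF sampling), processes the earliest
event, and redraws all timers after every event and at every phase
boundary — statistically neutral for the memoryless geometric law, and
faithful to the recalculation of intervals after each change in `S`. The
chain is defined per-step (Bernoulli per site), so waiting times are
geometric, the discrete-time analogue of exponential intervals.
Simultaneous draws are resolved uniformly at random, one change at a time.
Cost scales with the number of events: one working-point connection over
10¹⁰ steps has only a handful of events. Per-connection RNG streams are
derived as `seed + index`, making population runs bit-reproducible.

**Information curves.** Mutual information between branches (initial
states, or applied conditions) and the evolved count is computed from
conditional distributions by total probability; stored conditionals can be
re-weighted under new initial distributions without re-simulation. Exact
propagation is the default — it removes plug-in estimator bias and makes
the decay analyses deterministic — while the population mode (empirical
frequencies, no bias correction) mirrors the stochastic procedure with 500
connections per initial state or 1500 condition draws and is used for
cross-validation. Threshold crossings (τ₀.₉₅, τ₀.₅₀) interpolate linearly
in log time, matching the exponential recording grid
(`round(1.2^k)`, deduplicated); a curve that never crosses returns `Inf`
("beyond horizon") rather than an error. The plateau reference for τ₀.₉₅
is the matched two-state information at `t = 0`, `H₂(q)` — an analytic
anchor that avoids fragile numerical plateau detection on log-time grids.
"Decayed to zero" is operationalized as MI < 10⁻³ bits where needed.

## The two-state reduction

The long-lived information is the peak identity, so the two peak masses
form a two-state chain with stationary `(1 − C*, C*)` and rate `R`. We
take `C*` as the upper-peak mass `Σ_{S>S̃} p_wp[S]` (not the mixture
weight `C`; they agree to ~10⁻³ for sharp peaks) and match `R` to the only
equilibrium flow between the peaks, across the barrier pair `(S̃, S̃+1)`:
`R = (N − S̃) b p_wp[S̃]` (ties in the interpeak minimum resolve to the
smallest `S`; the matched rate depends only on `p_wp[S̃]`, which is
tie-invariant). The exponential solution of the two-state chain is treated
as the continuous-time envelope of the discrete chain; at `R ~ 10⁻¹⁰` per
step the discretization is far below every tolerance used.

The same barrier flow quantifies the advantage over a mono-synaptic
connection: the decay is
`((N − S̃) p_wp[S̃] / Σ_{S≤S̃} p_wp[S])⁻¹`-fold slower — the inverse
lower-peak exit flux per unit lower-peak mass, ≈155 at the defaults. This
reading of the compact slowdown expression is internally consistent
(monotone in the barrier depth, invariant under rescaling `b`) and is
unit-tested as such.

A caveat the tests make explicit: the barrier-flow matching *overestimates*
the exact slowest relaxation rate of the full chain by ~1.5× at the
default peak geometry (4.2·10⁻¹⁰ vs 6.5·10⁻¹⁰ per step), because the
barrier state participates in both peaks' local equilibria. The matched
two-state information curve therefore deviates from the exact one by up to
~0.07 bits during the second decay — visually negligible on a log-time
axis spanning ten decades, but larger than a 0.05-bit tolerance. The
corresponding acceptance test asserts the 0.05-bit figure and fails
honestly; the matching formula itself is implemented in its stated barrier-flow form.

## Calibration to experimental days

Experiments report ~5% newly formed, persistent spines per day under
control conditions. The model analogue is the probability that a
connection forms a synapse during a window of `T` steps that survives to
the window's end (assuming at most one formation per window):
a geometric-series closed form in the formation rate `f = (N − S + 1) b`
and deletion rate `r = S d[S]`, summed over formation times (the closed
form corresponds to formation times `0 … T−1`; powers are evaluated via
`log1p` to keep the brute-force comparison at 10⁻¹² through `T = 10⁴`).

The expectation convention matters. We take the numerator over
pre-formation counts `S − 1` drawn from the working-point stationary
distribution *conditioned on a formation being possible* (`S − 1 ≤ N − 1`,
renormalized) and divide by the unconditioned stationary mean `E[S]` — the
expected number of pre-existing synapses. At the calibration
parameterization (`N = 5`, `σ = 1.2`) this fraction rises through 5% at
~8·10⁵ steps, peaks near 8%, and falls back through 5% at
`T ≈ 2.15·10⁷` steps/day — the experimentally relevant crossing, since
windows comparable to a day lie on the falling branch where new synapses
are already being lost again. The solver therefore brackets the peak and
bisects the falling branch. The fully "joint" convention (unnormalized
numerator) is available as an alternative mode and crosses at
~1.9·10⁷. Re-fitting `T` against raw experimental spine counts is out of
scope (external data); only the analytic solver ships.

## Protocols

**Decay.** Each initial state evolves under one fixed condition;
`MI(S(0); S(t))` is tracked on the exponential grid. Initial conditions:
the working-point distribution itself, the two-delta distribution
(`p[0] = 1 − C`, `p[N] = C`), and the piecewise-uniform distribution
(`1 − C` spread over `{0, 1, 2}`, `C` over `{4, …, N}`; the boundary count
`S = 3` sits between the stated peak supports and is excluded by
default, assignable by configuration).

**Learning/retention.** Phase 1 equilibrates in the working point — in
exact mode the branch simply starts at the stationary distribution, which
is what "long enough that initial conditions have no influence" converges
to; in population mode initial states are drawn from it. Phase 2 drives
each branch by a condition drawn with probabilities `P(ℑ)` (uniform by
default) until converged (checked by total variation < 10⁻⁶, warning
otherwise); phase 3 reverts to the working point. `MI(S(t); ℑ)` yields
τ₀.₅₀ of each phase and their ratio ΔT. Exact weighting is the default;
the 1500-draw sampled mode reproduces the randomized protocol.

At the default parameters the exact computation gives
τ₀.₅₀(learning) ≈ 1.7·10⁷, τ₀.₅₀(retention) ≈ 7.3·10⁸, so ΔT ≈ 42:
learning indeed completes before retention starts decaying, but the ratio
is ~1.6 orders of magnitude, not 2–3. The structural reason is visible in
the rates: retention cannot outlast the across-peak relaxation
(~1/4·10⁻¹⁰ steps), while the learning rise is limited by synapse
formation into the upper peak (~2·10⁷ steps); both scale as `1/b`, so the
ratio is `b`-invariant. The package also reports the per-phase times to
reach stationarity (TV < 0.01), whose ratio is ~38 at the defaults. The
acceptance test for the two-to-three-order claim is left failing rather
than redefining the measure.

**Retraining.** The in-vivo motor-learning timeline: 30 days working
point, 16 days early training, 74 days working point, 8 days late
training, at `T = 2.3·10⁷` steps/day, `N = 5`, `σ = 1.0`. During training
4.35% of connections receive `low`- and 0.65% `high`-stimulation (the
same connections in both phases of the retraining paradigm); control never
trains; late-only trains only in the last 8 days. The population size is
set so the expected initial synapse count is 160, and 8 seeded replicates
mirror the typical number of animals. Created/removed synapses per day are
counted from the overlap of occupied sites on consecutive days. The
quantitative comparison to the experimental turnover bars requires the
external spine-count data and is out of scope; the tests assert the
qualitative signature — late-only turnover exceeds control, retraining
stays at control level (the early training's structural trace persists).

**Sweeps.** τ₀.₉₅ (and ΔT) over grids of `λ, μ, σ, C`, with non-bimodal
cells flagged rather than fatal. The monotonicities — longer storage for
narrower (`σ`, `λ` small) and better separated (`μ` large) peaks, weak
dependence on `C` — are asserted cell-wise in the tests. Sweeps default to
the two-delta initial condition, whose information curve is entirely
plateau, so τ₀.₉₅ isolates the across-peak decay.

## What the simulator does and does not emulate

The event-driven ensemble is a synthetic population of statistically
identical, non-interacting connections with homogeneous sites, constant
formation rate, and instantaneous condition switches. It reproduces the
master equation by construction (verified at total variation ≤ 0.05 with
5000 connections across all conditions) and the turnover bookkeeping of
imaging experiments (site overlap between observation days). It does not
model activity or synaptic weights, spatial dendritic structure, per-site
heterogeneity, developmental non-stationarity (the over-expression of
spines in young animals), or activity-dependent formation rates — so
agreement of tests on synthetic data shows internal consistency of the
stochastic machinery, not realism of those omitted features.

## Problem sizes

The analyses in the tests and the acceptance script run at the study
conditions themselves: state spaces of 6–11 counts, exact propagation to
10¹²–10¹³ steps (a single 8×8 eigendecomposition each), 5000-connection
ensembles for simulator validation, and the full 128-day retraining
timeline at 2.3·10⁷ steps/day with ~300 connections × 8 replicates × 3
paradigms (about a minute, dominated by the event loop). Nothing is scaled
down relative to the reference protocols except the per-test ensembles of
the unit suite, which use moderate-rate toy chains where only the
stochastic machinery, not the time scale, is under test.

## Known limitations

* The two-state matching is a barrier-flow approximation; its rate error
  (~1.5× at the defaults) grows as the interpeak minimum becomes shallow.
* The calibration expectation convention is a modelling choice with no
  unique first-principles answer; both conventions are exposed and the
  default is documented above.
* `interpeak_minimum` requires exactly two local maxima; distributions
  with plateaus or more structure are rejected rather than guessed at.
* The discrete-time chain has no continuous-time variant here; all rates
  are probabilities per step.
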