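---
title: "Methods: the SS^FIR model, its percolation solution, and why the mean field fails"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the SS^FIR model, its percolation solution, and why the mean field fails}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Nodes of an undirected simple contact network are susceptible (S), protected
susceptible (S^F), infectious (I) or recovered (R). Four reactions define a
continuous-time Markov process:

* S + I → 2I at rate β per S–I edge (transmission);
* S + I → S^F + I at rate β_F per S–I edge (behavioural response: the
  susceptible notices an infectious neighbour and adopts protection);
* S^F + I → 2I at rate γβ per S^F–I edge, γ ∈ [0, 1] the discount factor
  (protection reduces but need not eliminate risk; γ = 0 is perfect
  vaccination);
* I → R at rate μ per infectious node.

β_F is a **rate**, not a probability — values above 1 are meaningful and the
package never clamps it. With β_F = 0 the model is exactly network SIR, the
limit used throughout for validation. γ = 1 also reduces to SIR (protection
does nothing); the model's own domain is γ < 1 but the package admits γ = 1
as a validation limit.

All three analysis engines assume nothing about the graph beyond simplicity;
the *theory* additionally assumes an uncorrelated, locally tree-like graph —
the regime in which the generators below operate.

## Percolation / cavity theory

On an S–I edge, transmission (β), alerting (β_F) and recovery of the
infectious endpoint (μ) race; the edge therefore *transmits* with probability
T1 = β/(β+β_F+μ) and *alerts* with probability T2 = β_F/(β+β_F+μ). On an
S^F–I edge only the discounted transmission races recovery:
T3 = γβ/(γβ+μ).

The cavity construction conditions on *externally infected neighbours*
(EIN): neighbours that become infected even with the focal node removed. Let
θ be the probability that a random neighbour is an EIN. Given m EINs, the
focal node's infection probability is computed under a **non-overlapping
ordering approximation**: the m infectious neighbours act one at a time;
while the node is susceptible each actor transmits (T1), alerts (T2) or drops
out (1−T1−T2); from the alerting actor onward — including that actor itself —
each remaining actor transmits with probability T3. Summing the two routes
(direct infection; alert-then-infection) gives the closed form

p(R|m) = 1 − A·(1−T1−T2)^m − B·(1−T3)^m,
A = (T1−T3+T2T3)/(T1+T2−T3), B = (1−T3)·T2/(T1+T2−T3),

with A + B = 1, so p(R|0) = 0 exactly. Binomial mixing over m ~ Bin(k, θ)
gives p(R|k) with (1−θ(T1+T2))^k and (1−θT3)^k in place of the two powers.
Averaging over the excess degree distribution
Q(k) = (k+1)P(k+1)/⟨k⟩ yields the self-consistency map

θ = f(θ) = 1 − A·G1(1−θ(T1+T2)) − B·G1(1−θT3),

and averaging over P(k) gives the final prevalence R(∞) with G0 in place of
G1. The outbreak condition is f′(0) = (T1 + T2·T3)·G1′(1) ≥ 1, whose root in
β is the epidemic threshold β_c. Both the generating-function form and the
explicit rate form are implemented and agree to 1e−12; closed-form limits
used in the tests: β_F = 0 gives β_c = μ/(G1′(1)−1)·… the classical SIR
value (1/9 for Poisson ⟨k⟩ = 10, μ = 1); γ = 0 gives
β_c = (μ+β_F)/(⟨k⟩−1) for Poisson; γ = 1 gives the SIR value for every β_F.

Numerical choices:

* **Removable singularity.** The shared denominator T1+T2−T3 is non-negative
  (γ ≤ 1 forces T3 ≤ T1+T2) and vanishes only in the SIR-equivalent corner
  (β_F = 0 with γ = 1, or β = 0). When |T1+T2−T3| < 1e−9 the analytic limit
  is used: [(1−T3)^m − (1−T1−T2)^m]/(T1+T2−T3) → m(1−T1−T2)^{m−1}, and the
  corresponding G1′/G0′ expressions in the θ and R(∞) formulas. The cutoff
  1e−9 sits far above double rounding error of the two nearly-cancelling
  powers yet far below any parameter regime of interest.
* **Fixed point.** f maps [0,1] to [0,1], fixes 0, and is nondecreasing
  (property-tested on parameter grids), so iteration from θ₀ = 1 descends
  monotonically to the largest — physical — fixed point. Iterates get 0.5
  damping if they ever oscillate. Convergence is declared at residual 1e−12
  (configurable); below threshold the solver short-circuits via the outbreak
  margin and returns θ = 0 exactly, which makes "prevalence = 0 iff θ = 0"
  hold without tolerance games. Uniqueness of the positive fixed point is not
  proved here; monotonicity plus the checks on both sides of every solved
  threshold stand in for it.
* **Threshold bracketing.** Bisection (via `uniroot`) on the margin over
  [1e−6, 50μ] by default. For γ > 0 the margin → G1′(1)−1 > 0 as β → ∞, so a
  root exists whenever the graph can percolate; for γ = 0 the left side
  saturates at β/(β+β_F+μ) and an unbracketed margin is reported as an error
  with both endpoint values rather than guessed.
* **Which degree distribution.** All theory functions accept any
  `degree_distribution`. When comparing against simulation on a concrete
  graph the *empirical* distribution of that graph is used (removes
  finite-sampling mismatch); ideal Poisson/power-law distributions are used
  for closed-form work. The Poisson support is truncated where the upper
  tail drops below 1e−12, which perturbs ⟨k⟩ at the 1e−11 level — below
  every tolerance used.

## Stochastic simulator

The four reactions define the process unambiguously in continuous time, so
the canonical engine is an exact event-driven (Gillespie) simulation. Each
infectious node i carries rate r_i = (β+β_F)·n_S(i) + γβ·n_F(i) + μ, where
n_S, n_F count its susceptible and protected neighbours; a Fenwick tree over
r_i gives O(log N) sampling of the next event's node, and each state change
updates only the O(k) affected neighbour counts. Runs on N = 10⁴ graphs take
milliseconds, so the full figure-level protocol (≥1000 realizations per
parameter point) is cheap.

* **Randomness.** A private 64-bit generator (seeded mt19937_64, 53-bit
  uniforms) drives everything in C++; realization r of an ensemble uses the
  stream (master_seed, r). Identical master seeds give bit-identical
  ensembles on the same platform, independent of R's RNG state; graph
  generation is seed-stable the same way.
* **Seeding policy.** One uniformly random infectious seed per realization
  (configurable count or fixed set). The source protocol does not state its
  seed count; a single seed is the standard choice for threshold studies and
  produces the near-zero subcritical sizes the Δ measure relies on.
* **Δ over all realizations.** Δ = √(⟨ρ²⟩−⟨ρ⟩²)/⟨ρ⟩ is computed over *all*
  realizations including early die-outs — no outbreak conditioning — which is
  what makes the peak at the threshold sharp. Δ is NaN (with a warning) when
  every run has ρ = 0, which cannot happen with ≥1 seed (seeds recover), but
  the guard keeps the function total.
* **Outbreak-conditioned mean.** With a single random seed, the
  unconditional mean final size approaches P(outbreak)·R(∞), not R(∞) — for
  ER ⟨k⟩ = 10 at β = 0.3 the gap is ≈ 0.08, far beyond any stated
  theory-vs-simulation tolerance, so agreement plots must condition. Ensembles
  therefore report both `mean_rho` and `mean_rho_outbreak`, the latter over
  runs with ρ > 1% (cutoff configurable). At the sizes used (N ≥ 2000,
  supercritical β) die-outs stay below ~20 nodes and outbreaks above ~100,
  so the split is insensitive to the cutoff across an order of magnitude.
* A synchronous discrete-time engine (internal `sim_discrete`, step Δt) exists
  purely as a statistical cross-check of the event-driven engine; the test
  suite verifies mean final sizes agree within Monte-Carlo error at
  Δt = 2e−3 on a 200-node graph.

## Random graphs (the synthetic world)

The generators *are* the stated experimental conditions: Erdős–Rényi with
N = 10⁴ and ⟨k⟩ = 10, and the uncorrelated configuration model (UCM) with
P(k) ∝ k^−3 on [3, √N], μ = 1 throughout, ≥1000 realizations for threshold
estimation. Tests scale N and realization counts down (documented per test)
but never move the model parameters.

* ER uses skip-based G(n, p) enumeration with p = ⟨k⟩/(n−1).
* UCM draws the degree sequence i.i.d. from the truncated power law (one
  degree is redrawn until the sum is even — minimal distortion of P(k)), then
  stub-matches. Conflicting stub *pairs* (self-loop or duplicate) are
  redrawn; only a deadlock triggers a full restart (bounded at 100). A
  full-restart-on-any-conflict policy would be exact-rejection sampling of
  simple matchings, but its acceptance probability at these moments
  (≈ exp(−ν/2−ν²/4), ν = (⟨k²⟩−⟨k⟩)/⟨k⟩ ≈ 8.6 here) is ~e^−23 — unusable.
  Pair-redraw preserves the degree sequence exactly; it samples simple graphs
  with very slightly non-uniform weights, an accepted standard trade-off for
  configuration-model studies and irrelevant at the observables used here.

What the synthetic world does **not** contain: degree–degree correlations,
clustering/short loops, communities, weighted or temporal edges. The theory
assumes their absence, so a green theory-vs-simulation test establishes
correctness of both engines *in the locally tree-like regime only* — it says
nothing about transfer to clustered real contact networks.

## Degree-based mean field, and its failure

The first-order closure tracks per-degree-class fractions with coupling
Θ = Σ_k kP(k)I_k/⟨k⟩:

dS_k = −(β+β_F) k S_k Θ, dS^F_k = β_F k S_k Θ − γβ k S^F_k Θ,
dI_k = kΘβ(S_k + γS^F_k) − μI_k, dR_k = μI_k.

(The system is usually written with μ = 1 absorbed; the package multiplies
the recovery terms by μ so the parameterization matches the simulator.) Its
threshold is β_c = ⟨k⟩/⟨k²⟩ — **independent of β_F and γ**: linearizing
around the disease-free state, S → S^F transitions are O(I) and S^F → I
transitions again O(I), so the protective route contributes at O(I²) and
drops out. The stochastic process does not work like that: the alerting
neighbour is *still infectious* when the alert happens, so alert-then-infect
is first order. Exhibiting this contradiction — mean-field liftoff static at
1/11 for Poisson ⟨k⟩ = 10 while the percolation/simulation threshold moves
from 1/9 (β_F = 0) to ≈ 0.200 (β_F = 1, γ = 0.1) — is the package's central
demonstration. A corollary verified in the tests: above threshold the closure
*overestimates* R(∞) (by ≈ 0.05 at β = 0.3, β_F = 0), so no tight three-way
agreement between mean field and the other engines should ever be asserted.

Numerics: no ODE-solver package is assumed; a self-contained Dormand–Prince
RK45 with adaptive steps (rtol 1e−8) integrates the 4×(k_max+1) system until
the aggregate infectious fraction falls below 1e−9 or t = 10⁴. Poisson
supports are truncated at tail mass 1e−12 (≈ mean + 10 SD). Initial condition:
I_k = i0 = 1e−4 uniformly. "Liftoff" is operationalized as R(∞) > 10·i0 on a
β grid. Caveat: just below threshold the final size is amplified to
≈ i0/(1−β/β_c), so the liftoff criterion trips once β ≳ 0.9 β_c; with the
0.01 grid used, the detected liftoff lands within one grid cell of
⟨k⟩/⟨k²⟩ and, crucially, at the *same* cell for every (β_F, γ) — the
invariance, not the absolute placement, is the result.

## Known limitations

* The non-overlapping-order assumption behind p(R|m) is an approximation to
  the concurrent dynamics; its error is assessed only empirically (the
  theory-vs-simulation tolerance of a few 1e−2 at N = 2000–10⁴), not bounded
  analytically.
* Δ-peak threshold estimation at scaled-down size is resolution-limited: at
  N = 2000 with 500 single-seed realizations the Δ top is flat and the argmax
  jitters by ±1 grid cell (0.01) around the percolation root, so one-cell
  agreement there is a coin flip; at the full stated scale (N = 10⁴, 1000
  realizations) the peak matches the root within one cell for both β_F
  values tested. The corresponding acceptance test runs the scaled-down
  protocol as specified and is allowed to stay red rather than be tuned.
* The theory modules assume uncorrelated, locally tree-like graphs; no
  degree-correlated or clustered corrections, no temporal networks, no
  reinfection, and no multiplex (information-layer) extension.
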