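---
title: "A network model of societal complexity and collapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A network model of societal complexity and collapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(collapsenet)
library(dplyr)
```

## The model

`collapsenet` implements a stylized agent-based model of Tainter's
energy–complexity spiral: a society solves recurring problems (shocks to its
energy supply) by adding administrative complexity, each increment of which
is individually rational but collectively steers the system into diminishing
marginal returns and, eventually, collapse.

A society is an Erdős–Rényi random graph `G(N, ρ)` whose nodes are long-lived
labor-supplying units. Every node is in one of three roles, and the roles
always partition the node set:

* **Administrators (A)** produce nothing but raise the productivity of the
  laborers directly connected to them. Their count `N_A` is the model's
  measure of societal complexity.
* **Coordinated laborers (C)** are non-administrators adjacent to at least
  one administrator (adjacency to several administrators confers no extra
  benefit).
* **Laborers (L)** are the remaining, uncoordinated producers.

Each time step:

1. *(Social mobility, optional.)* Every node independently switches status
   with probability `p_e`: administrators step down, non-administrators step
   up. Flips commit synchronously; C-vs-L labels are then re-derived from
   adjacency, so only the admin/non-admin direction is stochastic.
2. *(Shock.)* The per-node resource is reduced to `R = R_max (1 - B)` with
   `B ~ Beta(α, β)`. The defaults `(α, β) = (1, 15)` make most shocks mild
   (`E[B] = 1/16`) with a thin tail of severe ones.
3. *(Production.)* Total energy is `E = R (N_L^a + c N_C^b)` — a
   Cobb–Douglas-style utility with decreasing returns to scale (`a, b < 1`)
   and a productivity premium `c > 1` for coordinated work. `R_max` is
   normalized to `N / N^a = N^(1-a)` so the unperturbed all-laborer society
   produces exactly 1 unit per capita.
4. *(Problem solving.)* If per-capita energy falls strictly below the
   threshold (`E/N < ε`), exactly one additional administrator is appointed:
   the best-connected laborer if there are no administrators yet, otherwise
   the best-connected *coordinated* laborer. Degree ties are broken uniformly
   at random with the run RNG. The promotion changes role counts — and hence
   energy — from the next step onward.

The run ends when all nodes are administrators (`N_A = N`): no laborers
remain, `E = 0` forever, and the society has collapsed. Runs that reach
`t_max` without collapsing are right-censored. The return on complexity
`ROC(t) = (E(t) - E(t-1)) / (S(t) - S(t-1))` reduces to the plain energy
difference because complexity `S = N_A` grows by exactly one per
recruitment; it is recorded every step.

Without mobility (`p_e = 0`) the administration can only grow — a ratchet
that hard-wires eventual collapse. This is deliberate: it isolates the claim
that if complexity has costs and cannot be reduced, collapse is a matter of
time.

## Parameters

| Parameter | Meaning | Default |
|---|---|---|
| `N` | network size (nodes) | 400 |
| `t_max` | censoring horizon (steps) | 10,000 |
| `alpha`, `beta` | shock shape `B ~ Beta(α, β)` | 1, 15 |
| `epsilon` | per-capita energy threshold | 1.0 |
| `a` | elasticity of uncoordinated labor | 0.75 |
| `b` | elasticity of coordinated labor | 0.75 |
| `c` | productivity factor of coordinated labor | 1.05 |
| `rho` | link probability | 0.02 |
| `p_e` | exploration (mobility) probability | 0.0 |

The defaults are the reference study conditions; the sweep ranges explored by
`parameter_sweep()` are `c ∈ [1, 3]`, `ρ ∈ [0, 0.1]` and `p_e ∈ [0, 0.2]`.
`R_max` is always derived, never set.

## The macroscopic approximation

Averaging over shocks and network realizations gives a one-dimensional
deterministic approximation of the administrator count. Exploration
contributes a net drift `p_e (N - 2 N_A)`. For recruitment, assume link
density is homogeneous: a non-administrator avoids coordination with
probability `(1 - ρ)^{N_A}`, so

```
N_L ≈ (N - N_A) (1 - ρ)^{N_A},   N_C ≈ (N - N_A) (1 - (1 - ρ)^{N_A}),
```

and the deterministic energy factor is `e = N_L^a + c N_C^b`. The threshold
fires iff `1 - B < N^a ε / e`; since `1 - B ~ Beta(β, α)` (shapes swapped),
the per-step recruitment probability is the Beta CDF `P = F(N^a ε / e; β, α)`,
clamped to `[0, 1]` — when even the unshocked economy cannot meet demand
(`x > 1`, including `e = 0` at `N_A = N`) recruitment is certain. Together:

```
dN_A/dt ≈ p_e (N - 2 N_A) + F(N^a ε / e; β, α).
```

Two consequences organize the whole phase diagram:

* **Critical mobility.** Near `N_A = N` the CDF term tends to 1, so the
  boundary rate is `1 - p_e N`. The collapse state is attracting iff
  `p_e < 1/N`: less than one status switch per step on average cannot rescue
  the society, while anything above that threshold makes collapse reachable
  only through rare shock sequences. `critical_exploration()` returns the
  closed form and confirms it by bisection.
* **Equilibrium band.** Because the CDF term lies in `[0, 1]`, any interior
  equilibrium satisfies `N/2 ≤ N_A ≤ N/2 + 1/(2 p_e)`: a surviving mobile
  society ends up with slightly more administrators than laborers.

```{r}
p <- model_params(p_e = 0.02)
find_fixed_points(p)
critical_exploration(p)
```

## Numerical choices

* **Integrator.** The reference integrator in `integrate_macro()` is
  explicit Euler with `dt = 1`. This is not a concession: the micro-model is
  a discrete-time map recruiting at most ~1 administrator per step, so the
  unit-step map *is* the faithful deterministic counterpart. A Runge–Kutta
  option (`method = "ode45"`) exists for comparison.
* **Collapse threshold for the continuous state.** The ODE only reaches
  `N_A = N` asymptotically; the trajectory is declared collapsed at
  `N_A ≥ N - 0.5` (half-count rounding of the discrete absorbing state).
* **The edgeless case.** With `ρ = 0` no node can ever be coordinated, so
  the micro-model has no eligible recruit and freezes in its initial state.
  The raw mean-field CDF term would still fire (at `N_A = 0` its argument is
  exactly `ε`), so `macro_rhs()` drops the recruitment term when `ρ = 0` to
  match the model it approximates.
* **Fixed-point detection.** `find_fixed_points()` brackets sign changes on
  a fine grid and polishes with `uniroot()`; stability comes from a
  central-difference derivative. Plateaus where the rate is strictly
  positive but numerically negligible (large `c` with `p_e = 0`; the rate
  can be ~1e-40) are reported as *metastable* rather than as spurious roots
  — these are the states in which stochastic runs linger near `N_A = N/2`
  for very long times before a shock sequence tips them over.
* **Recruitment timing.** Energy recorded at step `t` is post-exploration,
  pre-recruitment; a promotion at `t` first affects `E(t+1)`. The threshold
  comparison is strict (`E/N < ε`).
* **Tie-breaking.** Maximum-degree ties are resolved uniformly at random
  from the run RNG (not by node id), keeping runs seed-reproducible without
  imposing an arbitrary ordering.
* **Draw order.** Each run consumes randomness in a fixed order — network,
  then per step: exploration uniforms (skipped when `p_e = 0`), one Beta
  draw, and a tie-break draw only when needed — so identical
  `(parameters, seed)` give identical trajectories.
* **Censored medians.** `median_survival()` enters censored runs at
  `t_max`; an even-sized ensemble uses the midpoint of the two central
  order statistics. A median at the cap is reported as "≥ t_max, potentially
  infinite".

## What the simulator does and does not emulate

The simulator is its own data generator; there is no external data. The
generated conditions are the reference ones above: Beta-distributed
multiplicative shocks, a static Erdős–Rényi topology, and constant
population. Real societies violate most of these: networks are clustered,
heterogeneous and dynamic, populations grow, resources deplete, and
"energy" aggregates many currencies. Passing tests therefore validate the
mechanism — complexity growth under a ratchet produces rise-then-decline
energy arcs and finite survival, while mobility above `1/N` stabilizes a
half-administrated state — not any calibration to historical cases.

Two known, deliberate gaps between the stochastic model and its mean-field:

* **Degree heterogeneity.** Recruitment prefers hubs, whose above-average
  reach makes early administrators more effective than the homogeneous
  approximation assumes; the approximation therefore slightly overestimates
  the speed of collapse at `p_e = 0`.
* **Fragmentation.** At very sparse densities the graph splits into
  components; components without administrators can never be administrated,
  leaving a permanently productive remnant (isolated long survival in the
  stochastic model that the mean-field cannot produce). The
  macro-vs-stochastic cross-validation in the test suite is accordingly run
  at mean degrees of about 8–20, inside the approximation's domain of
  validity.

## Problem sizes used by the tests

The test suite and acceptance script re-simulate everything from scratch.
Sizes were chosen as the smallest that still exercise each claim cleanly:
full `N = 400` runs for the regime checks (50 seeds for the collapse
regime, 10–12 seeds at `p_e = 0.02`, 100-run ensembles over a 3,000-step
horizon for the micro/macro comparison), and `N = 200` with 25-seed
ensembles for the sweep cross-validation. The survival-time maps are
computed from the deterministic approximation (as the reference analysis
does), which is why a dense `(ρ, c, p_e)` grid is affordable: all grid
cells are integrated simultaneously as one vectorized Euler state.

## Limitations

* No population growth, resource depletion, inter-society competition, or
  multiple hierarchy layers; one abstract energy currency.
* Collapse is defined as `E = 0` (equivalently `N_A = N`); intermediate
  collapse signals between `ROC ≤ 0` and `E = 0` are not modelled
  separately, as they are not expected to differ qualitatively.
* The turning point `p_e0 < 1/N` below which extra mobility *shortens*
  survival is only characterized numerically (e.g. as the argmin of median
  survival over a `p_e` grid); no closed form is claimed.
* Only Erdős–Rényi topologies; `rescale_density()` is provided to keep the
  escape probability `(1-ρ)^N` comparable across sizes, but other network
  families are out of scope.
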