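---
title: "Methods: sparrow search, good point sets, and constrained resource allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparrow search, good point sets, and constrained resource allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparrowalloc)
```

# The problem

Public-health education programs distribute scarce resources — teaching
materials (R1), staff (R2), facilities (R3), and IT support (R4) —
across regions or institutions. Concentrating a resource where it is
most "efficient" maximizes short-term effect but produces inequitable
coverage; spreading it uniformly is equitable but wasteful. This package
formalizes the trade-off as a constrained allocation problem and solves
it with a population metaheuristic, the sparrow search algorithm (SSA),
improved by a deterministic low-discrepancy initialization and an
elite-guided position refresh (ISSA).

# The allocation model

For one resource category with $n$ targets, a candidate allocation is a
share vector $x = (x_1, \dots, x_n)$. Feasibility requires

$$\sum_a x_a = 1,\qquad x_a \ge 0,\qquad \sum_a x_a^2 \le \delta^2,
\qquad LB_a \le x_a \le UB_a,$$

and the objective maximized is the weighted effect
$f(x) = \sum_a \omega_a\, g_a(x_a)$, with per-target efficiencies $E_a$
entering through the effect curves $g_a$: linear ($E_a x$), saturating
($E_a(1 - e^{-\kappa x})$), or power ($E_a x^\gamma$).

The cap $\delta^2$ on the *second moment* $\sum x_a^2$ is the model's
equity knob. It is written as a variance cap because, on the simplex,
$\sum x_a^2 = 1/n + n\,\mathrm{Var}(x)$ up to scaling: capping one caps
the other. Its admissible range is $[1/n, 1]$ — the uniform allocation
attains the minimum $1/n$, a one-hot allocation attains 1. We implement
the cap exactly as a second-moment bound rather than a central-moment
variance, because that is the form the constraint takes in the model;
the two differ only by the affine transformation above.

Balance is reported as Jain's fairness index
$J(x) = (\sum x_a)^2 / (n \sum x_a^2)$, a standard 0–1 equity measure.
The model's own constraint ties the two together: on the simplex
$J = 1/(n \sum x_a^2)$, so any feasible allocation has
$J \ge 1/(n\delta^2)$. A variance cap is thus exactly a balance floor,
which is why we chose this index among the many fairness measures — it
is the one the constraint already speaks about.

The four categories are optimized independently (one problem each):
staff sent to one region cannot simultaneously teach in another, while
digital materials can be shared, so pooling categories into one
parameter would average away exactly the structure that matters. The
`shareable` flag records this distinction; in the generator it tightens
the per-target upper bound for location-bound categories (default
$UB = 0.5$ versus $1.0$), and it is metadata elsewhere — the
mathematics is identical across categories.

## Constraint handling: repair, not penalties

Candidate positions proposed by the optimizer are mapped to feasibility
*before* evaluation ("repair"), rather than penalized. Penalty terms
introduce a weighting parameter whose tuning is itself a research
problem, and with an exact cheap repair available the repaired search
space is simply the feasible set. Repair composes three steps:

1. clamp to the box $[LB, UB]$;
2. Euclidean projection onto the intersection of the simplex with the
   box — solved exactly: the projection is
   $x = \mathrm{clip}(v - \theta, LB, UB)$ where $\theta$ solves the
   piecewise-linear equation $\sum \mathrm{clip}(v_a - \theta, LB_a,
   UB_a) = 1$, found by sorting the $2n$ breakpoints (for the plain
   simplex, $LB = 0$, $UB = 1$, this reduces to the classic
   sorted-threshold projection, exported as `project_to_simplex()`);
3. if $\sum x_a^2 > \delta^2$, shrink toward uniform:
   $u + t(x - u)$ with $u = 1/n$ and
   $t = \sqrt{(\delta^2 - 1/n)/(\sum x_a^2 - 1/n)}$, which stays on the
   simplex, preserves the ranking of shares, and meets the cap with
   equality.

Step 2 is deliberately the *box-aware* projection rather than a plain
simplex projection: projecting after a clamp can push a coordinate back
above its upper bound, and solutions must satisfy every constraint
family simultaneously. Problem validation requires the box to admit the
uniform vector ($LB_a \le 1/n \le UB_a$); combined with
$\delta^2 \ge 1/n$ this guarantees a nonempty feasible set and makes
step 3 safe (a convex combination of two in-box points stays in the
box). Repair is idempotent, which the test suite checks on random
vectors.

## The exact oracle

For linear effects the problem — maximize $\sum x_a E_a$ over the
capped simplex — has a closed-form solution via the KKT conditions. On
the optimal support $S$, stationarity gives
$x_a = 1/|S| + (E_a - \bar E_S)/(2\mu)$ with the ball multiplier
determined by $\sum x_a^2 = \delta^2$; the support is a top-$k$ prefix
of the targets sorted by efficiency. `kkt_oracle_linear()` enumerates
all $n$ prefixes and returns the best feasible candidate — exact in
$O(n^2)$, independent of the metaheuristic, and itself cross-checked
against exhaustive grid search (`grid_oracle_linear()`, step $10^{-3}$)
on small instances. This dual route (stochastic solver vs analytic
oracle) is the package's primary correctness argument.

# The optimizer

## Baseline SSA

A population of $N$ candidate positions is split each iteration into
three behavioral roles by fitness rank: the best $\lceil PD \cdot N
\rceil$ are *discoverers* (producers), $\lceil SD \cdot N \rceil$
random non-discoverers are *scouts*, and the rest are *followers*
(scroungers). Discoverers either shrink multiplicatively
($X \cdot e^{-\mathrm{rank}/(uT)}$, $u \sim U(0,1]$, probability $ST$)
or take a shared normal step ($X + Q$, $Q \sim N(0,1)$). Worst-half
followers migrate ($Q \cdot e^{(X_\mathrm{worst} - X)/r^2}$); best-half
followers move next to the best position
($X_\mathrm{best} + |X - X_\mathrm{best}| \cdot A/d$, random signs
$A$). Scouts move a uniform-random fraction toward the best position.
All moves are clamped to the bounds (clamping, not reflection, so
positions "remain within the effective range"); ties in fitness break
to the lowest index for reproducibility.

The role-update formulas beyond the scout rule are the canonical SSA
producer/scrounger rules from the metaheuristics literature; the model
description we implement states only the generic form
$X_\mathrm{new} = X + \Delta X$, which underdetermines $\Delta X$.
Defaults: $PD = 0.2$, $SD = 0.1$, $ST = 0.8$ — the values commonly used
for SSA — all configurable in `optimizer_config()`.

## The ISSA layer

Two mechanisms are added:

**Good-point-set initialization.** The starting population is the
classical good point set $\{(\{\gamma_1 k\}, \dots, \{\gamma_d k\}):
k = 1..N\}$, $\gamma_j = \mathrm{frac}(2\cos(2\pi j/p))$ with $p$ the
smallest prime $\ge 2d + 3$, mapped affinely onto the bounds. It is
deterministic — ISSA's iteration-0 population is identical for every
seed — and covers the cube more evenly than uniform sampling. We
quantify "more evenly" by a Monte-Carlo estimate of the star
discrepancy (exact computation is NP-hard in $d$): the maximum over
4096 random anchored boxes $[0, a)$ of |empirical fraction − volume|.
At 1000 points the good point set beats the mean of 20 random sets in
both $d = 2$ and $d = 5$ (20/20 paired wins in our suite). The
advantage is asymptotic in $n$ for fixed $d$ — its discrepancy bound
decays like $\log(n)^d/n$ against $n^{-1/2}$ for random points — so it
has *not* set in at, say, 100 points in 5 dimensions, where the lattice
stripes make the estimate worse than random; the vignette notes this
deliberately, and the uniformity tests assert the property only in the
regime where the construction is expected to hold.

**Elite-guided refresh with fitness-preserving acceptance.** After the
role updates of each iteration, every sparrow receives a proposal

$$X' = X + \alpha\,(P_\mathrm{best} - X) + \beta\,(r - 0.5)\,(UB - LB),
\qquad r \sim U(0,1)^d,$$

a pull of strength $\alpha$ toward the best position found so far plus
a zero-mean uniform perturbation scaled by $\beta$ and the per-dimension
range (fresh draw per dimension). The proposal replaces the sparrow
*only if it improves its fitness*. This acceptance rule is the
mechanism by which the elite set "preserves the positions with higher
fitness": without it, a constant-scale perturbation applied
unconditionally would floor the attainable precision at the noise
scale ($\sim \beta \cdot \mathrm{range}$), destroying exactly the
late-stage refinement the elite pull is meant to provide. With it, the
elite stage is a monotone local search layered on SSA — it can only
help a sparrow, never hurt it — at the cost of one extra objective
evaluation per sparrow per iteration ($N(2T+1)$ total versus
$N(T+1)$ for SSA).

The elite *set* (top $\lceil qN \rceil$ by fitness, with its centroid)
is refreshed by re-selection from the freshly evaluated population each
iteration rather than interpolated: selection is the mechanism that
moves the set toward better regions, and combining interpolation with
the guided move would double-step the same relaxation. Whether the
guiding point should be the elite centroid or the single best member is
genuinely open in the model description; we use the best position
(`P_best`), the choice consistent with the update formula's own
notation, and expose the centroid for users who want it.

Defaults $\alpha = 0.5$, $\beta = 0.3$, $q = 0.2$: no values are
prescribed by the model description; $\alpha = 0.5$ halves the distance
to the best per accepted move, $\beta = 0.3$ makes the perturbation
reach about a third of the search range so the move stays useful for
escaping local basins, and under greedy acceptance the performance is
robust to these choices (rejected proposals cost one evaluation, not
progress).

## Numerical choices

* Internal sense is minimization; `maximize` objectives are negated at
  the `objective()` boundary (single code path).
* One shared `rand` across dimensions in the scout rule (the update is
  a scalar convex combination along the segment to the best), fresh
  per-dimension `rand` in the elite move (a space-filling perturbation).
* All randomness in a run derives from `cfg$seed` via R's RNG;
  `withr::with_seed` isolates runs, so fixed seeds give bit-identical
  results and the caller's RNG state is untouched.
* Clamping at bounds everywhere; repair (not clamping) inside
  `solve_allocation()`, where the feasible set is not a box.
* Best-so-far history is recorded once per iteration (length $T$), so
  convergence curves are comparable across algorithms with different
  per-iteration evaluation counts.

# The scenario generator

`generate_scenario()` emulates multi-region, four-category allocation
instances: efficiencies log-uniform on $[0.5, 2]$ (a 4:1 ratio between
the most and least efficient target — a realistic spread for regional
capacity differences, and symmetric on the log scale), weights uniform
or Dirichlet, the variance cap uniform over its admissible range
$[1/n, 1]$ (spanning easy, nearly unconstrained regimes and hard,
near-uniform ones), and tighter upper bounds for the location-bound
categories. `generate_with_known_optimum()` pairs a random linear
instance with its exact KKT solution, making end-to-end recovery
testable without any external data.

What the generator deliberately does **not** emulate: real allocation
data with correlated efficiencies and weights, demand that shifts over
time (the model is single-period), integer or indivisible resources
(shares are continuous), and inter-category coupling (categories are
independent problems). Passing the recovery tests therefore shows the
optimizer solves the *stated model* to oracle accuracy — it does not
validate the model itself against field data, which no public dataset
for this setting exists to support.

# Platform scores

Two weighted-sum metrics accompany the allocation model in the
information-platform layer: a content-push score $C_i = \sum_j U_{ij}
P_j$ ranking educational content by user-group affinity under a push
strategy, and a satisfaction score $S = \sum_i Q_i W_i$, a convex
combination of per-service quality ratings. Both are linear in their
weight vectors; the push ranking is invariant to positive rescaling of
the strategy, and satisfaction is bounded by the quality range. The
index pairing in the source formulas is ambiguous as printed; we
implement the only reading under which they are well-formed — aligned
elementwise products summed over one index.

# Problem sizes used in the test suite

The distributed test suite runs the oracle-equivalence study at 50
problems ($n \in \{3, 5, 10\}$, $N = 30$, $T = 300$), the paired
SSA/ISSA comparison at 20 seeds ($d = 10$, $T = 500$), and the
discrepancy study at 1000 points with 20 random baselines — the same
sizes `scripts/acceptance.R` recomputes. Module tests use smaller
instances chosen to exercise every branch rather than to demonstrate
performance.

# Known limitations

* With `delta_sq` near 1 and near-tied top efficiencies the optimum
  sits at a simplex vertex; the repaired search concentrates there
  slowly, and a handful of instances in the oracle-equivalence study
  end above the $10^{-3}$ relative gap (the median is orders of
  magnitude below it).
* The KKT oracle covers linear effects only; for saturating/power
  effects correctness rests on the exhaustive grid oracle at small $n$
  and on qualitative properties (monotone resource response).
* The good-point-set advantage needs $n$ large relative to $d$ (see
  above); for high-dimensional problems with small populations the
  initializer is no worse than one random draw, but its uniformity
  rationale does not apply.
* SSA's multiplicative producer shrink biases search toward the origin;
  on benchmark functions whose optimum sits at the origin (sphere,
  Rastrigin) this flatters *absolute* performance of both SSA and ISSA.
  The SSA-vs-ISSA comparison is paired per seed precisely so this
  shared bias cancels out of the contrast.
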