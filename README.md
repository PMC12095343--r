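# sparrowalloc

Constrained allocation of public-health education resources with an
improved sparrow search algorithm (ISSA).

Health-education programs split scarce resources — teaching materials,
staff, facilities, IT support — across regions or institutions. Pure
efficiency-maximization concentrates everything in the strongest
region; pure equity spreads everything uniformly. `sparrowalloc`
formalizes the trade-off and solves it:

* **Model.** An allocation is a share vector `x` on the probability
  simplex (`Σx_a = 1`, `x_a ≥ 0`) with per-target box bounds and a
  concentration cap `Σx_a² ≤ δ²` — a second-moment ("variance") bound
  that acts as an equity floor: on the simplex, Jain's fairness index
  equals `1/(n·Σx²)`, so the cap guarantees balance `≥ 1/(nδ²)`. The
  objective maximized is the weighted effect `Σ ω_a·g_a(x_a)` with
  linear, saturating, or power effect curves scaled by per-target
  efficiencies `E_a`.
* **Optimizer.** The sparrow search algorithm (SSA) — a population
  metaheuristic with discoverer / follower / scout roles — plus the two
  ISSA improvements: a deterministic *good-point-set* initialization
  (`γ_j = frac(2cos(2πj/p))`, `p` the smallest prime `≥ 2d+3`) whose
  star discrepancy beats random starts, and an *elite-guided refresh*
  `X' = X + α(P_best − X) + β(rand − ½)(UB − LB)` accepted only when it
  improves fitness.
* **Ground truth.** For linear effects the exact optimum follows from
  the KKT conditions (`kkt_oracle_linear()`, itself cross-checked by
  exhaustive grid search), so solver accuracy is measured, not assumed.
* **Infrastructure.** A scenario generator with known analytic optima,
  a benchmark harness with paired-seed SSA-vs-ISSA comparison,
  content-push and satisfaction scores for the surrounding information
  platform, tidy/glance/autoplot methods, CSV/JSON/YAML I/O, and a CLI.

## Worked example

Generate a five-region scenario, solve the shareable-materials category
with ISSA, and compare against the exact optimum:

```r
library(sparrowalloc)

sc   <- generate_scenario(scenario_spec(n_regions = 5, seed = 42))
prob <- sc$R1
prob
#> <allocation_problem> R1 (shareable): 5 targets, delta_sq = 0.6153

sol <- solve_allocation(prob,
                        optimizer_config(pop_size = 30, max_iter = 300,
                                         seed = 1),
                        algorithm = "issa")
sol
#> <allocation_solution> ISSA on R1 (5 targets)
#>   objective: 0.363689   balance: 0.3251   feasible: TRUE

tidy(sol)
#> # A tibble: 5 × 5
#>   target_id efficiency weight        share        effect
#> 1 region1        1.78     0.2 0.260        0.0924
#> 2 region2        1.83     0.2 0.740        0.271
#> 3 region3        0.743    0.2 0.0000000255 0.00000000379
#> 4 region4        1.58     0.2 0.0000000255 0.00000000807
#> 5 region5        1.22     0.2 0.0000000255 0.00000000621

orc <- kkt_oracle_linear(prob$targets$efficiency, prob$delta_sq)
(orc$value / prob$n - sol$objective_value) / (orc$value / prob$n)
#> [1] 2.384962e-08
```

The solver splits the budget between the two most efficient regions —
full concentration is forbidden by the cap `δ² = 0.615` — and lands
within 2.4×10⁻⁸ (relative) of the exact KKT optimum. The balance score
0.3251 sits exactly at the model's guaranteed floor
`1/(n·δ²) = 0.3251`: the solution is as concentrated as equity permits,
which is where a linear objective pushes.

Benchmarks and convergence curves:

```r
rep <- run_benchmark(c("sphere", "rastrigin"),
                     cfg = optimizer_config(max_iter = 200),
                     seeds = 1:5, d = 10)
glance(rep)            # median/IQR final fitness per algorithm
paired_comparison(rep) # per-seed SSA-vs-ISSA win counts
autoplot(rep)          # median convergence curves
```

Command line (installed under `exec/`):

```sh
sparrowalloc simulate --n-regions 5 --seed 3 --out scenario/
sparrowalloc optimize --problem scenario/R1 --out solution
sparrowalloc score --satisfaction 8,6 --weights 0.7,0.3
```

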