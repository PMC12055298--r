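# netews

Spatial early warning signals (EWSs) for tipping points of stochastic
dynamics on networks.

Networked systems — ecosystems, epidemics, gene circuits — can cross a
bifurcation and jump to a qualitatively different state as an environmental
parameter drifts. Temporal EWSs (variance or autocorrelation of a time
series at one location) need many samples per environmental condition.
Spatial EWSs need only **one sample per node**: a single snapshot of the
node states, aggregated over the network. `netews` is a toolkit for
quantifying how well six such signals anticipate tipping points, for anyone
studying regime shifts on networks or benchmarking EWSs.

## What it does

* Simulates four stochastic dynamics models on connected, undirected,
  unweighted graphs by Euler–Maruyama integration (Rcpp core): a coupled
  double-well model, mutualistic species dynamics, an SIS epidemic model
  and gene-regulatory dynamics, each with its standard parameters, noise
  level and lower/upper node-state rule.
* Runs control-parameter sweeps (`run_sweep()`): at each of L = 100 grid
  values of the coupling strength D or uniform stress u, the system is
  re-initialized, integrated for 50 time units at dt = 0.01, and one
  equilibrated snapshot x\* is kept. The **home range** — grid points
  before the first node tips — is extracted (`find_home_range()`), and a
  usable simulation range can be found automatically
  (`search_simulation_range()`).
* Computes six spatial EWSs per snapshot (`compute_ews()`): Moran's I

  I_M = (N/W) · Σ_ij A_ij (x_i − x̄)(x_j − x̄) / Σ_i (x_i − x̄)²,

  the spatial standard deviation s (N−1 denominator), spatial variance m₂
  (N denominator), coefficient of variation CV = s/x̄, sign-adjusted
  skewness g₁′ = ±m₃/m₂^{3/2} and raw kurtosis g₂ = m₄/m₂².
* Scores each EWS (`evaluate_sweep()`): sign-adjusted Kendall τ′ over the
  latter half of the home range, and a slope-ratio classification from OLS
  slopes over the first five (a) and last five (b) home-range points —
  *accelerating* (a>0, b>0, b/a>θ), *reversing* (a<0, b>0, |b/a|>0.5θ) or
  *unsuccessful*, with θ = 2.
* Aggregates across the ten retained (model, control, direction)
  conditions and arbitrary networks (`run_experiment()`, `rank_scores()`,
  `success_fraction()`), including the reference square-lattice experiment
  (`reproduce_lattice_experiment()`).

Synthetic networks (lattice, Barabási–Albert, Erdős–Rényi, Watts–Strogatz,
configuration model) are generated in-package; empirical networks are read
from plain edge-list files (`read_edge_list()`).

## Worked example

One ascending sweep of the coupled double-well model (control parameter u)
on the 10 × 10 periodic lattice, scored for all six EWSs:

```r
library(netews)
net  <- make_periodic_lattice(10)
spec <- model_spec("double_well", control = "u")
cfg  <- sweep_config(c(0, 3.2), "ascending", L = 100, seed = 1)
sw   <- run_sweep(spec, net, cfg)
sw
#> <sweep_result> double_well / u / ascending
#>   100 grid points in [0, 3.2], 100 nodes
#>   home range: first 81 grid points

evaluate_sweep(sw, net)[, c("ews_id", "tau_prime", "slope_a", "slope_b", "category")]
#>         ews_id tau_prime   slope_a  slope_b     category
#> 1      moran_i    0.1049 -9.46e-01  0.56858 unsuccessful
#> 2   spatial_sd    0.7171  5.45e-04  0.08712 accelerating
#> 3  spatial_var    0.7171  4.05e-05  0.00879 accelerating
#> 4           cv    0.4951 -2.37e-03  0.04160    reversing
#> 5 skewness_adj   -0.0512 -3.37e+00 -0.25856 unsuccessful
#> 6     kurtosis    0.0927 -9.20e+00 -0.38839 unsuccessful
```

Reading: all 100 nodes stay in the lower well for the first 81 of 100 grid
values of u (the home range); the first tipping occurs just past u ≈ 2.56.
The variance-family signals rise sharply toward the tipping point
(τ′ ≈ 0.72 for s and m₂, with accelerating slope ratios), CV dips then
recovers (*reversing* — still a successful warning), while Moran's I,
skewness and kurtosis fluctuate around their baselines on this
structurally homogeneous lattice and are classified unsuccessful.

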