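---
title: "Spatial early warning signals for tipping points on networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial early warning signals for tipping points on networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netews)
```

## The problem

Many networked systems — ecosystems, epidemics, gene circuits — sit on a
stable branch of states that can disappear abruptly as an environmental
parameter drifts past a bifurcation: a tipping point. Temporal early warning
signals (variance, autocorrelation of a time series at one location) need
many samples per environmental condition. Spatial EWSs instead take **one**
sample per node of the network at each condition and aggregate over nodes.
This package simulates tipping scenarios on networks and measures how well
six spatial EWSs anticipate the transition.

## Dynamics models

Four stochastic models run on a connected, undirected, unweighted simple
graph with adjacency matrix $A$. Each node state $x_i$ obeys an SDE
$dx_i = f_i(x)\,dt + \sigma\,d\xi_i$ with independent Gaussian noise per
node, where the drift $f_i$ is:

* **Coupled double-well** (saddle-node tipping between a lower well at
  $r_1$ and an upper well at $r_3$):
  $f_i = -(x_i - r_1)(x_i - r_2)(x_i - r_3) + D\sum_j A_{ij} x_j + u$,
  with $r_1 = 1 < r_2 = 3 < r_3 = 5$ and $\sigma = 0.1$.
* **Mutualistic species** (collapse of an extant assemblage past an Allee
  threshold): $f_i = B + x_i(1 - x_i/K)(x_i/C - 1) +
  D\sum_j A_{ij}\, x_i x_j / (\tilde D + E x_i + H x_j) + u$, with
  $B = 0.1$, $K = 5$, $C = 1$, $\tilde D = 5$, $E = 0.9$, $H = 0.1$,
  $\sigma = 0.001$.
* **SIS epidemic** (transcritical threshold between disease-free and
  endemic): $f_i = -\mu x_i + D\sum_j A_{ij}(1 - x_i)x_j$, with $\mu = 1$,
  $\sigma = 0.001$; $D$ is the infection rate and the only control
  parameter (a uniform stress has no epidemiological meaning here).
* **Gene-regulatory** (loss of the active expression state):
  $f_i = -B x_i^f + D\sum_j A_{ij}\, x_j^h/(1 + x_j^h) + u$, with $B = 1$,
  $f = 1$, $h = 2$, $\sigma = 0.001$.

The control parameter is either the coupling strength $D \ge 0$ or the
uniform stress $u$; the other is held at a model-specific default
(`model_spec()` documents them). States of the mutualistic, SIS and gene
models are clamped at zero after every integration step — negative
abundance, probability or expression is unphysical — while the double-well
coordinate is never clamped. Nodes are labelled *lower*/*upper* by
per-model thresholds: $x < r_2$ for the double well, $x \le C$ for the
mutualistic model, $x < 5\sigma$ for SIS and gene dynamics.

One sentence in the mutualistic state rule required a decision: the natural
threshold is the Allee constant $C$, and we classify $x_i \le C$ as lower
and $x_i > C$ as upper, consistent with the direction of every other
model's rule.

## Sweep protocol

A sweep (`run_sweep()`) traverses $L = 100$ evenly spaced values of the
control parameter. At **every** grid value the system is re-initialized at
the model's standard initial state (no continuation between grid points) and
integrated by Euler–Maruyama with $\Delta t = 0.01$ for 50 time units; the
single snapshot $x^*$ at $t = 50$ is kept — one sample per node, the
defining constraint of a spatial EWS. Ascending sweeps start in the lower
state and increase the parameter; descending sweeps start in the upper
state and decrease it. The noise update is $\sigma\sqrt{\Delta t}\,z$ with
standard-normal $z$; each grid point draws from its own deterministic child
stream of the sweep seed, so changing $L$ does not shuffle noise across
unrelated points.

The **home range** is the leading run of grid points at which every node is
still in its initial class; it ends just before the first tipping point.
All EWS evaluation is restricted to it, because after the first transition
the statistics of already-tipped nodes stop being informative about the
remaining ones.

The simulation range must bracket the first tipping point and leave the
home range long enough to score. `search_simulation_range()` automates the
choice: a coarse 20-point pilot sweep is run and the range is expanded (no
tipping), shifted (tipped at the start), or zoomed (tipped too early, the
far end pulled in so the tipping value sits about 70% of the way through)
until the pilot home range covers at least 40% of the grid.

## The six EWSs

From each snapshot $x^*$ we compute: Moran's $I$ (graph spatial
autocorrelation, the one EWS needing the adjacency matrix), the sample
standard deviation $s$ (denominator $N-1$), the spatial variance $m_2$
(denominator $N$ — deliberately a distinct statistic from $s^2$), the
coefficient of variation $CV = s/\bar x$, sample skewness
$g_1 = m_3/m_2^{3/2}$ and raw kurtosis $g_2 = m_4/m_2^2$ (no excess-3
adjustment). Because a warning can appear as increasingly *negative* skew
in descending sweeps, the scored series is $g_1' = g_1$ (ascending) or
$-g_1$ (descending). Rows where a statistic is undefined (constant states;
zero mean for CV, flagged below $10^{-12}$) are recorded as missing and
excluded pairwise downstream.

## Scoring

Two complementary scores are computed per EWS series over the home range of
length $k$:

* **Sign-adjusted Kendall $\tau'$** over the last $\lceil k/2 \rceil$
  home-range points (the informative end): $\tau' = \tau$ for ascending and
  $-\tau$ for descending sweeps. Ties use the $\tau_b$ convention, the
  common default in this literature.
* **Slope-ratio classification**: OLS slopes over the first five ($a$) and
  last five ($b$) home-range points, with the regressor negated for
  descending sweeps so that "rising toward the tipping point" is positive
  in both directions. With $\theta = 2$: *accelerating* if $a > 0$,
  $b > 0$, $b/a > \theta$; *reversing* if $a < 0$, $b > 0$,
  $|b/a| > 0.5\,\theta$; otherwise *unsuccessful*. A home range shorter
  than 10 points would make the windows overlap and yields a distinct
  "undetermined" error, not "unsuccessful". An exactly zero $a$ fails both
  strict inequalities and is unsuccessful.

Across conditions, `rank_scores()` awards 5 points to the best EWS per
condition down to 0 for the worst, averaging ties, and
`success_fraction()` reports the share of accelerating-or-reversing
classifications.

## The condition matrix and the lattice experiment

Of the 16 nominal (model, control, direction) combinations, ten are
retained (`enumerate_conditions()`): the mutualistic and gene models are
only simulated descending, and SIS has no $u$. The package's reference
experiment (`reproduce_lattice_experiment()`) runs all ten on the
$10 \times 10$ periodic lattice ($N = 100$, every degree 4) and summarizes
each EWS by its success count out of 10 and its mean $\tau'$ over the
successful subset.

The shipped simulation ranges (`lattice_conditions()`) are package choices,
seeded by a mean-field fold analysis of the degree-4 lattice and then
verified by `search_simulation_range()` under a fixed seed. One condition
needs a parameter exception: with the default $u = 0$, the descending-$D$
double-well system can never tip — the coupling input $D\sum_j A_{ij}x_j$
is non-negative, so the upper equilibrium persists all the way to $D = 0$.
We therefore run that condition at $u = -4$, just below the isolated-node
upper fold at $u \approx -3.08$, which makes the upper branch
coupling-dependent and restores a collapse at moderate $D$.

```{r lattice, eval = FALSE}
out <- reproduce_lattice_experiment(master_seed = 1)
out$summary
```

With one master seed this takes roughly half a minute on one CPU
(10 sweeps x 100 grid points x 5000 Euler steps x 100 nodes).

## Synthetic EWS curves

`make_ews_curve()` generates archetypal noise-free trajectories —
convex rise ($t^3$), decline-then-rise ($(t-0.3)^2$), fast-rise-then-plateau
($1 - e^{-10t}$) and gentle decline — whose classifications are known by
construction for any grid length of at least 10. They test the classifier
independently of any simulation, and with `noise_sd > 0` probe its noise
sensitivity.

## What the generator emulates — and what it does not

Synthetic networks (`make_model_network()`) cover homogeneous
(lattice, Erdős–Rényi, Watts–Strogatz) and heterogeneous (Barabási–Albert,
configuration-model) degree structure at the $10^2$–$10^3$ node scale, with
disconnected draws coerced to their largest component. The Barabási–Albert
default `m = 2` gives mean degree about 4, comparable to the lattice.
Passing tests on these graphs shows the machinery is correct and that
degree heterogeneity drives the expected EWS behaviour; it does not certify
performance on empirical networks with community structure, degree
correlations or weights, which users can supply as edge lists
(`read_edge_list()` coerces them to the required simple undirected form).

## Numerical choices and limitations

* Euler–Maruyama with $\Delta t = 0.01$ and a fixed 50-unit horizon,
  snapshot exactly at the horizon; no equilibration test is applied, by
  design (the fixed-budget protocol is part of what is being evaluated).
* Divergent states (non-finite) abort a sweep with the step and parameter
  value named; in multi-cell experiments the failure is contained to its
  cell (`status` column), never fatal.
* Classification counts on the **square lattice** are intrinsically noisy:
  all nodes are structurally equivalent, so snapshot distributions are
  nearly symmetric and skewness/kurtosis hover around their noise-centred
  baselines; their 5-point window slopes — and hence success counts and the
  sign of small mean $\tau'$ values — can flip between seeds on marginal
  conditions. The reference experiment therefore reports stochastic
  quantities, and replicate master seeds (medians of counts, pooled
  $\tau'$) are the recommended way to consume them.
* Deterministic bifurcation analysis, hysteresis (continuation) sweeps,
  temporal EWSs, spatially correlated noise and online stopping rules are
  out of scope.
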