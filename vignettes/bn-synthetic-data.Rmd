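---
title: "Probabilistic synthetic data for discrete Bayesian networks: models, diagnostics, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic synthetic data for discrete Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnsynth)
```

## The model

`bnsynth` simulates the *forward problem* of Bayesian-network analysis:
given a network model, produce data. A model has three layers:

1. **Structure.** A directed acyclic graph over `n` discrete variables. We
   generate structures as edge subsets of the upper triangle of an adjacency
   matrix under a topological ordering, so acyclicity holds by construction
   and never needs checking. The maximum edge count is `D = n(n-1)/2`; the
   number of structures with exactly `d` edges is `choose(D, d)`, so under
   uniform sampling of edge subsets the density is Binomial(D, 1/2) and
   mid-density structures dominate the space. This combinatorial bias is a
   property of the model space itself; any benchmark built on "random DAGs"
   inherits it, which is why the package exposes it quantitatively
   (`density_pmf()`, `config_count()`) and offers a fixed-density regime.
2. **Local distributions.** Each node carries a conditional probability
   table: a column-stochastic matrix with one column per joint assignment of
   the node's parents (one column for a root). Columns are sampled from a
   Dirichlet distribution on the probability simplex; with concentration
   `alpha = 1` the columns are uniform on the simplex.
3. **The joint.** The network factorizes the joint distribution as
   `P(X1, ..., Xn) = prod_i P(Xi | parents(Xi))`, which is computed exactly
   by enumeration (`enumerate_joint()`) and sampled exactly by ancestral
   sampling (`sample_dataset()`): nodes are visited in topological order and
   each state is drawn from the table column its sampled parents select.

## Dependence as a matrix property

Viewing a table `D` as a linear operator mapping the parent distribution `q`
to the child marginal `p = D q` makes the dependence relationship
prior-free:

* the child is conditionally dependent on its parents **iff** `rank(D) >= 2`
  (`is_dependent()`); a rank-1 table maps every prior to the same marginal;
* `p` always lies in the convex hull of the columns;
* the columns that are *vertices* of that hull are the structurally
  dependent parent events — those whose conditional differs from the
  marginal under every full-support prior (`hull_vertices()`); rank `r`,
  vertex count `d` and column count `m` obey `r <= d <= m`.

`build_cpt(n_vertex_columns = k)` exploits the geometry: `k` columns are
free Dirichlet draws and the rest are random convex combinations of them, so
at most `k` structurally dependent events exist. The event-wise definition
of dependence (some column differs from `D q`) is retained as
`dependence_oracle()` and the test suite verifies the two criteria agree on
thousands of random tables — the rank test is never trusted on its own.

Two edge cases are interpreted deliberately. A column that is *not* a hull
vertex can still differ from the marginal under a *particular* prior; we
therefore read vertex columns as *structurally* dependent events (dependent
under every full-support prior) rather than as the only events that can ever
exhibit dependence. And a rank-1 table has a single-point hull with one
vertex yet zero dependent events, so the vertex-count/dependent-event
correspondence is only applied when rank is at least two.

## Markov-blanket inference

The blanket of a center `X` contains its immediate ancestors `a(X)`,
immediate descendants `d(X)`, and co-ancestors
`ad(X) = a(d(X)) - X - a(X) - d(X)`. Every parent of a descendant is by
definition a member, so the joint over the members decomposes exactly as

```
P(M) = P(X | a(X)) * prod_{Y in d(X)} P(Y | a(Y)) * Phi(M - X)
```

where `Phi` collects the factors of the upstream members and of any
out-of-blanket nodes they depend on, summed over the out-of-blanket states.
A fully per-node factorization of `Phi` (a product of each upstream member's
conditional) would *not* be exact in general: out-of-blanket common
ancestors can correlate upstream members, and a co-ancestor can itself be a
non-immediate descendant of `X` or a child of another member. `bnsynth`
therefore evaluates `Phi` by exact summation over the out-of-blanket
ancestral closure (`blanket_joint_table()`). Crucially, no factor inside
`Phi` can involve `X` — a child of `X` is always a member — so `Phi` cancels
in `center_conditional()` and the conditional keeps the clean table-factor
form. The headline test of the module checks, on batches of random models,
that `P(X | M - X)` equals the brute-force conditional on *all* other
variables to 1e-10: the Markov property itself is the acceptance surface.

Zero-probability periphery assignments raise a typed error
(`bnsynth_undefined_conditional`) rather than returning NaN or a uniform
fallback; silent imputation would mask model defects.

## The entropy bias of naive generation

Flat-Dirichlet table columns do **not** produce flat descendant marginals.
For a binary child of a binary parent, the mixed component
`z = t p + (1 - t) q` (columns `p`, `q`, prior weight `t`, all flat) has
density `f(z) = 2(-z log z - (1 - z) log(1 - z))` — twice the binary entropy
(`entropy_density()`, verified by simulation in `prop1_simulation()` and by
quadrature). As the number of mixed columns grows, each component of the
induced marginal is a randomly weighted sum of Beta(1, m-1) variables with
mean `1/m` and variance `(m-1)/(m^2 (m+1))` (`beta_column_moments()`), and
its distribution concentrates and approaches normality
(`clt_experiment()`). The consequence for simulation studies:
descendant-node marginals pile up near the maximum-entropy center of the
simplex, and low-entropy terminal configurations become practically
inaccessible. `fig1_replication()` makes the effect measurable as the gap
between mean root and terminal marginal entropies across replicate networks.
The experiment tests mean recovery, variance shrinkage and qualitative
normality, not the limiting variance constant of the underlying central
limit theorem — that constant depends on conditions of the cited limit
theory that the package does not re-derive. We expose `alpha` but prescribe
no corrective concentration schedule; correcting the bias is out of scope.

## Parameters that matter

| Parameter | Where | Default | Rationale |
|---|---|---|---|
| `n` nodes, `arities` | `random_bn()` | 8 nodes, tertiary | reference configuration of the simulation experiments: large enough for 6561 joint events, small enough to enumerate instantly |
| density regime | `sample_dag()` | `prob`, `p = 0.8` | "average edge density 0.8" is realized as independent per-edge inclusion with probability 0.8; configurable to `uniform` or `fixed` |
| `alpha` | `build_cpt()` | 1 (flat) | uniform sampling of simplex columns; the value under which the entropy-bias results hold |
| `n_vertex_columns` | `build_cpt()` | off | caps structurally dependent events; minimum 2 (dependence needs two hull vertices) |
| JSD base | `jsd()` | 2 (bits) | bounded by 1 and conventional; base is configurable since only the scale, not orderings, depends on it |
| event-space cap | `enumerate_joint()` | 1e7 | exactness is the design point: above the cap the package errors instead of approximating |
| `seed` | all stochastic entry points | none | one global R stream; the same seed reproduces outputs byte-identically |

Node labels default to `X1..Xn` in topological order; a random label
permutation is available (`permute_labels = TRUE`) but off by default to
keep outputs immediately readable and reproducible.

## Numerical choices

* **Rank tolerance.** `is_dependent()` uses the standard numerical-rank
  cutoff `max(n, m) * eps * sigma_max` on singular values; the theory speaks
  of exact rank, floating point does not.
* **Hull vertex test.** Per-column convex-combination feasibility is decided
  by non-negative least squares on the column system augmented with the
  sum-to-one row (Lawson–Hanson, `pracma::lsqnonneg`); the global optimum of
  this convex problem has residual ≈ 0 exactly when a representation exists.
  This is robust in degenerate and low-dimensional cases and gives a
  per-event answer. Duplicate columns are collapsed to one representative
  before testing (two identical columns would otherwise trivially represent
  each other and both fail the strict test), and all duplicates of a vertex
  representative are reported as vertices — the geometric hull is preserved.
* **Categorical draws** use inverse-CDF with states accumulated from state 0
  upward, fixing the tie-break and making output reproducible across
  platforms given the same generator stream. One stream serves the whole
  dataset rather than per-node streams: a simpler reproducibility contract.
* **Degenerate Dirichlet draws.** Vertex-capped table construction verifies
  rank ≥ 2 and redraws on failure (bounded at 100 retries, then a typed
  error). Rank deficiency has probability zero for continuous draws, but
  floating point exists.
* **Tables are prior-free.** Conditional columns are defined for every
  parent event regardless of whether the event has positive probability
  under any ancestor distribution (the ratio definition of conditional
  probability breaks down at zero-probability events; the operator view does
  not), so no special-casing is needed anywhere downstream.
* **Exact integer counts.** Structure-space counts use a small
  arbitrary-precision integer type (base-1e7 digit vectors): `choose(120, 60)`
  is on the order of 1e35 and the closure identity `sum_d C(D, d) = 2^D`
  is checked exactly, not in floating point.
* **Sample-size search** (`required_sample_size()`) walks a doubling grid
  and bisects between the last failing and first passing size. The
  exceedance probability `P(max_i |N p_i - x_i| > delta)` is estimated by
  seeded multinomial replicates (default) or bounded by a sum of per-event
  binomial tails; the union bound is conservative, and the search treats the
  Monte-Carlo estimate as if monotone in N, which holds up to replicate
  noise.

## What the generator emulates — and what it does not

The synthetic models emulate the *probabilistic* content of biological
networks: arbitrary discrete dependence structures with exactly known joint
distributions, spanning the model space in a quantified (if deliberately
biased) way. They do not emulate measurement noise, missingness, mixed
continuous/discrete variables, feedback loops, or marginal distributions
matched to a particular assay. Passing tests therefore demonstrate that the
machinery is exact and statistically sound under its own assumptions — not
that any particular biological dataset looks like its output. Mixed-type
models are a deliberate non-goal, as is the inverse problem (structure
reconstruction) and any use of local prediction accuracy as a structure
search objective.

## Problem sizes used in the tests

The test suite runs the dependence sweep on 10^3 random tables with 10
priors each, the blanket-vs-brute-force comparison on 100 random models of
up to 6 nodes and arity 3, the mixture law on 10^5 draws, the entropy-bias
experiment on 10^4 replicate 8-node tertiary networks, and the JSD
convergence on 20 replicas each of N = 10^2, 10^4, 10^6 rows — sizes at
which every check is exact or statistically decisive while the whole suite
stays comfortably interactive. Structure-uniformity checks use 10^5 draws
against the closed-form density distribution (chi-square at alpha = 0.01).

## Known limitations

* Exact computation is capped by event-space enumeration (product of
  arities); there is no variable-elimination backend for larger models, by
  design.
* Fixed-density sampling is uniform *within* a density stratum, but forced
  uniform sampling *across* strata is not offered: the extreme-density
  strata are so sparse relative to mid-density ones that maintaining a
  constant sampling rate across strata is computationally impractical for
  all but the smallest models.
* The entropy-bias experiment redraws the network structure for every
  replicate (the cloud then reflects the generator's full randomness); a
  fixed-structure variant is a flag away in user code by seeding
  `sample_dag()` separately.
* `wilcox.test`/KS-based diagnostics are statistical: at the documented
  sizes their verdicts are overwhelming, but they remain hypothesis tests,
  not proofs.
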