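# bnsynth

Fully probabilistic synthetic-data generation for discrete Bayesian networks.

Benchmarking a network-inference method — in computational systems biology or
anywhere else graphical models are reconstructed from flat data — requires
synthetic datasets whose generating distribution is known exactly and whose
model space is sampled in a statistically understood way. `bnsynth`
implements such a forward simulator end to end:

* **Random DAG structures.** Edges are drawn in the upper triangle of an
  adjacency matrix over a topological ordering, so acyclicity is structural.
  Three density regimes are supported: uniform over all 2^D edge subsets
  (D = n(n−1)/2), uniform over the C(D, d) structures of fixed density d, and
  independent per-edge inclusion with probability p. Structure counts are
  computed in exact arbitrary-precision integer arithmetic, and the density
  distribution P(δ(G) = d) = C(D, d)/2^D is available in closed form.
* **Conditional probability tables as simplex columns.** Each node's CPT is
  an n × m column-stochastic matrix whose columns are Dirichlet(α) draws on
  the probability simplex. The dependence structure a table encodes is a
  property of the matrix alone: the child depends on its ancestors iff the
  matrix has rank ≥ 2, the induced marginal P(X) = D·P(Y) always lies in the
  convex hull of the columns, and the hull's vertex columns are the
  structurally dependent ancestor events (rank r, vertex count d and column
  count m satisfy r ≤ d ≤ m). `build_cpt()` can cap the number of hull
  vertices to control the proportion of dependent events.
* **Exact ancestral sampling** of datasets of any size, and **exact joint /
  marginal computation** by enumerating the factorized joint
  P(∩X_i) = ∏ P(X_i | parents(X_i)).
* **Markov-blanket inference.** `blanket()` extracts a node's immediate
  ancestors, descendants and co-ancestors; `center_conditional()` computes
  P(X | M − X) from the factored blanket joint, which provably equals the
  conditional given *all* other variables.
* **Distributional diagnostics.** Jensen–Shannon divergence between
  empirical and analytic joints, multinomial sample-size bounds
  P(max_i |N·p_i − x_i| > δ) < ε, and the entropy-bias diagnostics: with
  flat-Dirichlet CPTs the marginal of a descendant node follows the
  non-uniform density f(z) = 2H(z) in the two-column case and drifts toward
  the maximum-entropy center of the simplex as ancestors multiply.

## Worked example

```r
library(bnsynth)

## reference configuration: 8 tertiary nodes, per-edge probability 0.8
model <- random_bn(8, arities = 3, mode = "prob", p = 0.8, seed = 42)
model
#> bn_model: 8 nodes (arities 3-3), 18 edges

## exact model-space combinatorics (16-node example)
as.numeric(config_count(16, 8))
#> [1] 840261910995

## sample a dataset and compare it with the analytic joint
data <- sample_dataset(model, 1e4, seed = 42)
rep <- analyze_dataset(model, data)
rep$jsd                  # Jensen-Shannon divergence, bits
#> [1] 0.06500577
c(rep$n_events, rep$n_observed_events)
#> [1] 6561 1831

## Markov-blanket inference
b <- blanket(model, "X4")
b
#> bn_blanket of X4: a = {X2,X3}, d = {X5,X6,X7,X8}, ad = {X1}
periph <- setdiff(b$members, "X4")
center_conditional(model, "X4", setNames(rep(0L, length(periph)), periph))
#> [1] 0.2034 0.2891 0.5075

## entropy bias of terminal vs root marginals
fig1_replication(2000, seed = 42)
#> bn_entropy_report: 2000 replicates
#>   mean entropy (nats): root 0.8406, terminal 1.0942
```

At N = 10^4 samples only 1831 of the 6561 joint events have been observed and
the divergence is still ≈ 0.065 bits; rerunning with N = 10^6 drives it
near 10^-3 — the convergence the JSD diagnostic quantifies. The entropy
report shows the systematic drift of terminal-node marginals toward the
simplex center (≈ 1.094 nats versus ≈ 0.841 for roots; the maximum for a
tertiary variable is ln 3 ≈ 1.099).

A thin command-line wrapper over the same functions ships in
`inst/cli/bnsynth` (subcommands `generate-model`, `sample`, `analyze`,
`blanket`, `diagnose`).

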