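---
title: "Stratified partial-correlation networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified partial-correlation networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratnet)
```

`stratnet` estimates and compares conditional-association networks for two
strata of one clinical cohort. This vignette is the package's account of
the statistical model, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the choices made where the design
was genuinely open.

## The estimation model

The 17 analysis variables (see `default_schema()`) are treated as one
joint system per stratum. Edge weights are *full* partial correlations:
the Pearson correlation matrix `R` is inverted and
`r_ij = -P_ij / sqrt(P_ii P_jj)` with `P = R^-1`, so each weight is the
linear association between a pair after regressing out the other 15
variables. This is the saturated (unregularized) Gaussian graphical model;
no shrinkage or EBIC-style model selection is applied, so sparsity comes
entirely from the significance screen described next.

Assumptions worth stating plainly:

* **Binary variables enter as 0/1 indicators.** Their "correlations" are
  point-biserial/phi coefficients, which attenuate relative to a latent
  continuous association. The network is therefore a network of *observed*
  indicators, not of latent traits; the synthetic generator reproduces
  exactly this regime (below).
* **Degrees of freedom.** p-values use `t = r sqrt(df/(1-r^2))` with
  `df = n - k - 2` where `k = 15` is the number of conditioned variables.
  At the default stratum sizes this gives df = 61 (n = 78) and df = 114
  (n = 131). Other df conventions exist (e.g. not subtracting the
  conditioned count); this one is exact for Gaussian data and is applied
  consistently, including in `edge_p_threshold()`.
* **Ordinal SES.** The social position index enters as a single
  ordinal-as-continuous score 1-5 (1 = high ... 5 = low), not as dummy
  variables: the network has one SES node.

## Edge retention: the p < 0.25 screen

`sparsify()` keeps exactly the pairs with two-sided `p < alpha`, strictly;
a boundary p-value equal to alpha is excluded. The default `alpha = 0.25`
is deliberately liberal: with 136 candidate edges most weights are near
zero, and the screen's purpose is parsimony of the drawn graph rather than
family-wise error control — absence of an edge is not evidence that the
association is zero. No multiple-testing correction is applied to edge
p-values, and by construction the retention rate for truly null edges *is*
alpha, a property the test suite exploits: under an independence design
the pipeline retains 25% of candidate edges (to within binomial noise),
which doubles as a calibration check of the p-value computation.
`edge_p_threshold(n, k, alpha)` reports the implied cut on `|r|`
(0.147 at n = 78, k = 15, alpha = 0.25).

## Graph statistics

Conventions follow what general-purpose network software (Gephi-style)
computes on such graphs:

* **Distances are unweighted hops.** Partial correlations are
  similarities, not costs, and integer diameters are the natural summary.
  Average path length is the mean over ordered, mutually reachable pairs.
* **Eigenvector centrality** runs power iteration on the absolute-weight
  adjacency, stops when the maximum componentwise change drops below 1e-8
  (cap 1000 iterations, error on non-convergence), and rescales so the
  maximum score is 1. A small diagonal shift (0.1 x the maximum row sum)
  is added before iterating: it leaves every eigenvector unchanged but
  breaks the +/- eigenvalue symmetry of bipartite topologies, which would
  otherwise make plain power iteration oscillate.
* **Closeness** for node `v` reaching `n_r` others at total distance `d`
  is `(n_r / d) * (n_r / (n - 1))` — reciprocal mean distance with a
  component correction so scores are comparable across disconnected
  graphs; isolated nodes score 0. The maximizer is reported as the
  *bridging node*, with ties broken by higher eigenvector centrality and
  then schema order.
* **Clustering coefficients** are the usual local triangle densities on
  the unweighted topology; nodes of degree < 2 score 0 and are excluded
  from the average.
* **Communities** come from a two-phase Louvain optimization of
  Newman-Girvan modularity on absolute weights (signed-modularity variants
  are nonstandard). Local moves visit nodes in a seeded shuffled order and
  accept the first strictly positive modularity gain; requiring strict
  improvement prevents cycling, and the seed makes run-to-run variation
  explicit. Resolution is fixed at 1 by default but exposed. Community ids
  are relabelled by decreasing size so output is stable. Negative weights
  only affect edge attributes, never the optimization.

Rankings everywhere break ties by schema order (stable sort), so output
is deterministic.

## The group-comparison battery

`table_one()` compares the strata variable by variable: uncorrected
Pearson chi-square with Cramér's `V = sqrt(chi2 / (N (min(r,c)-1)))` for
binary variables, pooled-variance (Student) t-tests with Cohen's
`d = (m1 - m0)/s_pooled` for continuous ones — pooled rather than Welch
because d is defined against the pooled SD and the two should share one
variance estimate. Finner's step-down adjustment
`p~_(i) = max_{j<=i} [1 - (1 - p_(j))^(m/j)]` is applied across the whole
family run in one invocation (m = 17 for the default schema); it is
monotone, the identity at m = 1, and uniformly less conservative than
Bonferroni, all of which are property-tested. Printed percentages use
half-up rounding to one decimal (135/209 = 64.6%).

Effect-size labels follow the conventional cutpoints `V > 0.20` /
`|d| > 0.50` for at least mild-moderate, with `V > 0.35` / `|d| > 0.80`
labelled moderate-large. One caveat worth knowing: for a 2x2 table with
the margins 36/95 vs 38/40 the uncorrected closed form gives V = 0.215,
which rounds to 0.21, not the 0.22 sometimes quoted for such tables from
bias-corrected or intermediate-rounded variants; `chi_square_test()`
reports the uncorrected value.

Degenerate inputs fail loudly rather than silently: zero margins in a
contingency table, zero pooled variance, constant columns, and numerically
singular correlation matrices (condition number above 1e10) are all
errors, the last naming the most collinear variables via their variance
inflation factors.

## The synthetic-cohort generator

`simulation_design()` specifies, per stratum, a symmetric
positive-definite *precision* matrix for a latent 17-dimensional Gaussian;
its off-diagonal support is the planted conditional-dependence graph, and
`planted_pcorr()` converts it to the implied partial correlations exactly.
The positive stratum additionally receives mean shifts on the
standardized (Cohen's d) scale. Binary variables are thresholded latent
coordinates, cut so each stratum hits its target marginal proportion; SES
is discretized to its 5 ordered levels from target marginals. Continuous
variables are then mapped to realistic reporting units by linear scaling,
which leaves every correlation untouched.

The default design *is* the study condition the package targets: 78 + 131
participants; planted supports of 60 (positive) and 68 (negative) edges
with distinct sparsity patterns; a hub on self-directedness in the
positive stratum (connected to 11 of 16 nodes) and on self-transcendence
in the negative stratum (13 of 16); a handful of strong edges
(|r| about 0.3, placed among truly continuous variables so discretization
cannot attenuate them); mean shifts of +0.45 to +0.55 d on impulsivity,
emotion dysregulation, distress and harm avoidance, -0.60 on
self-directedness, +0.25 on age; and binary margins such as 48.7% vs 27.5%
female. Where the emulated study reports no value (comorbid-disorder and
suicidal-behavior rates, scale means/SDs), defaults are realistic clinical
choices fixed once: mental-disorder comorbidity 45% vs 25%, suicidal
behavior 30% vs 15%.

What the generator deliberately reproduces: the attenuation and slight
p-value miscalibration induced by Pearson-correlating thresholded
indicators, the ordinal coarsening of SES, and stratum-specific structure.
What it does not emulate: non-Gaussian marginal shapes (skewed symptom
scores), missing data, measurement error in scale totals, and any
dependence between the stratum flag and the latent structure beyond mean
shifts and margins. Passing tests therefore certify the pipeline's
statistical machinery under a faithful-but-idealized data-generating
process; they are not a claim that a particular empirical network is
recoverable from 78 patients.

`recovery_experiment()` wraps the full estimate-then-threshold chain over
a grid of sample sizes: at n = 5000 the strong planted edges are retained
with sensitivity 1 and estimated within 0.05; at n = 78 many weak planted
edges fall below the 0.147 retention threshold, which is exactly the
small-sample behavior the liberal alpha is meant to mitigate.

## Problem sizes used in validation

The test suite and acceptance script run entirely on simulated data at
sizes chosen to make Monte-Carlo tolerances meaningful while staying
desk-scale: 100 seeded cohorts for the precision-vs-residual-regression
oracle (every entry to 1e-10), 200 random graphs of up to 20 nodes for the
centrality/clustering/modularity oracles, exhaustive modularity
enumeration (all set partitions, up to Bell(8) = 4140) for Louvain
optimality on graphs of 5-8 nodes, 200 replicates for the null
edge-retention calibration, 500 for the battery's type-I rate, and 3
replicates at n = 5000 for strong-edge recovery.

## Known limitations

* The saturated GGM needs `n > k + 2`; strata below 20 participants are
  refused and small strata warned about, but estimates near that boundary
  are noisy — by design the package mirrors a screening analysis, not a
  regularized estimator.
* Pearson treatment of binary nodes understates latent associations; a
  polychoric or mixed graphical model is out of scope.
* Louvain is a greedy heuristic: a single seed can miss the modularity
  optimum on adversarial graphs. The package exposes the seed; across 20
  seeds on small graphs the best run attains the exhaustive optimum and
  the spread in Q stays below 0.02.
* Exact reproduction of any specific empirical network is not a goal:
  without patient-level data, the planted designs are qualitative
  emulations of structure, not re-creations.
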