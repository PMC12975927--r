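# stratnet

Stratified partial-correlation networks for clinical cohorts.

`stratnet` is for clinical researchers who want to compare the *structure*
of associations among a fixed panel of patient variables across two strata
of one cohort — the motivating use case being patients with behavioral
addictions split by the presence (FA+) or absence (FA−) of comorbid food
addiction, measured on 17 variables: 4 sociodemographic (sex, age, marital
status, social position index), 6 psychopathology measures (impulsivity,
emotion dysregulation, global distress, comorbid mental disorder, suicidal
behavior, duration of the addictive problem) and the 7 TCI-R personality
dimensions.

## The model

Each stratum is modelled as a Gaussian graphical network over the `p = 17`
variables. Edge weights are full partial correlations: with `R` the Pearson
correlation matrix and `P = R⁻¹` its precision,

    r_ij·rest = −P_ij / √(P_ii · P_jj)

so an edge is the association between two variables after controlling for
all 15 remaining variables. Each weight gets a two-sided p-value from
`t = r √(df / (1 − r²))` with `df = n − k − 2` (`k = 15` controls), and the
network keeps exactly the edges with `p < 0.25` — a deliberately liberal
screen that trades specificity for sensitivity, on the view that the
absence of an edge is not evidence of a zero association. At the FA+ sample
size (n = 78) this retains edges with `|r| ≳ 0.147`.

On the retained graph the package computes:

* **density** — retained edges / 136 potential edges;
* **average path length and diameter** — unweighted hop distances;
* **eigenvector centrality** ("relevance") — power iteration on absolute
  weights, max-normalized;
* **closeness centrality** ("bridging capacity") — reciprocal mean
  distance with component correction; its maximizer is the *bridging node*;
* **communities** — seeded Louvain modularity optimization on absolute
  weights;
* **activation views** — a node's partition of the remaining nodes into
  connected ("activated") and unconnected ("deactivated") sets.

Alongside the networks, a descriptive battery compares the strata variable
by variable (uncorrected Pearson χ² with Cramér's V for binary variables,
pooled-variance t-tests with Cohen's d for continuous ones) with Finner's
step-down correction `p̃_(i) = 1 − (1 − p_(i))^(m/i)` across the family.

Because patient-level data of this kind are rarely shareable, the package
includes a first-class synthetic-cohort generator: a latent Gaussian model
with stratum-specific sparse precision matrices (the planted
conditional-dependence structure), standardized mean shifts, and binary
variables produced by thresholding their latent coordinate at cut points
that hit target marginal proportions. Every downstream stage is validated
against this generator: planted-edge recovery, null calibration of the
`p < 0.25` rule, and brute-force oracles for every graph statistic.

## Worked example

```r
library(stratnet)

cohort   <- generate_cohort(default_design(), seed = 1)  # 78 FA+ / 131 FA-
analysis <- run_stratified_analysis(cohort, seed = 1, quiet = TRUE)
analysis
#> <stratnet analysis> alpha = 0.25, seed = 1
#>
#> <stratnet report> stratum FA+ (n = 78)
#>   edges: 38  density: 0.279  avg path length: 1.890  diameter: 3
#>   communities: 4 (Q = 0.233)
#>   most relevant node: TCI.directed   bridging node: TCI.directed
#>
#> <stratnet report> stratum FA- (n = 131)
#>   edges: 52  density: 0.382  avg path length: 1.669  diameter: 3
#>   communities: 3 (Q = 0.205)
#>   most relevant node: TCI.transcen   bridging node: Emotion
```

The FA+ report recovers the design's planted hub: self-directedness
(`TCI.directed`) is both the most relevant node (highest eigenvector
centrality) and the bridging node (highest closeness); its network splits
into 4 communities versus 3–5 for FA−, and its density (0.279) is the
fraction of the 136 possible edges that survived the `p < 0.25` screen at
n = 78. The group battery flags the planted stratum differences after
Finner correction:

```r
dplyr::filter(analysis$comparisons$comparisons, p_adjusted < 0.05)
#> # A tibble: 7 × 8
#>   variable     test       statistic    df    p_raw p_adjusted effect_size effect_label
#>   <chr>        <chr>          <dbl> <dbl>    <dbl>      <dbl>       <dbl> <chr>
#> 1 Sex.Male     chi_square     18.9      1 1.35e-5    0.000230       0.301 mild-moderate
#> 2 Impulsivity  t_test          2.99   207 3.12e-3    0.0132         0.428 below
#> 3 Emotion      t_test          2.82   207 5.30e-3    0.0179         0.403 below
#> 4 Psy.Distress t_test          3.23   207 1.45e-3    0.00821        0.462 below
#> 5 TCI.harm     t_test          2.34   207 2.04e-2    0.0487         0.334 below
#> 6 TCI.persis   t_test         -2.40   207 1.71e-2    0.0478        -0.344 below
#> 7 TCI.directed t_test         -3.40   207 8.17e-4    0.00692       -0.486 below
```

Results can be written as Gephi-compatible GEXF/GraphML plus JSON reports
(`run_stratified_analysis(..., out_dir = "results/")`), plotted with
`autoplot()` / `plot_centrality()`, or driven from a shell via the wrapper
in `inst/scripts/stratnet.R` (subcommands `simulate`, `compare`, `network`,
`run`, `report`).

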