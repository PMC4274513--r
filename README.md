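# primatenet

Comparative analysis of social-network efficiency in animal groups.

Group-living primates move information through their social ties, and the
shape of a group's association network — how dense, how centralised, how
clustered — determines how well information can spread. `primatenet`
implements the full workflow for comparing network efficiency across
groups and species: per-group network statistics computed from weighted,
symmetrized association matrices; a synthetic cohort generator for testing
the pipeline end to end; and the comparative statistics used to relate
efficiency to species traits while accounting for shared ancestry.

## The statistics at its core

For a group of `N` individuals with `I` connections (pairs with positive
symmetrized weight) and binary shortest-path distances `d_ij` with
diameter `D`:

- **Edge density** `I / (N(N-1)/2)` — observed over possible
  relationships.
- **Global Efficiency** `E1 = N / (I * D)` — how completely the group is
  reachable through few connections.
- **Average Dyadic Efficiency** `E2 = mean over pairs of 1/d_ij` — 1 on a
  complete network; disconnected pairs contribute 0.
- **Centralisation index**
  `CI = 100 * sum_i (C_max - C_i) / S*(N)`, from eigenvector centralities
  `C_i`, with `S*(N)` the same sum on an `N`-node star — a star scores
  100, an egalitarian network 0, and fragmented networks exceed 100.
- **Maximum modularity** `Q` — best-partition within-cluster weight
  fraction minus its degree-sequence expectation (leading-eigenvector
  optimizer with deterministic refinement).

The comparative stage fits each efficiency on log group size, sex ratio,
neocortex ratio and CI with genus-within-family random intercepts (REML or
Bayesian MCMC), builds a correlation ledger under the Holm step-down
sequential Bonferroni correction, tests variance homogeneity across
contexts (Brown–Forsythe), and measures phylogenetic signal with
Blomberg's K and a permutation test.

## Worked example

```r
library(primatenet)

# one group's grooming network: a central female plus weaker ties
ids <- c("ana", "bob", "cleo", "dan", "eva")
W <- matrix(0, 5, 5, dimnames = list(ids, ids))
W["ana", c("bob", "cleo", "dan", "eva")] <- c(6, 4, 3, 5)
W[, "ana"] <- W["ana", ]
W["bob", "cleo"] <- W["cleo", "bob"] <- 2
net <- weighted_network(W, group_id = "demo_group",
                        interaction_type = "grooming")
compute_metrics(net)
#>     group_id N I density diameter  E1   E2       CI Q path_mode
#> 1 demo_group 5 5     0.5        2 0.5 0.75 92.87816 0    binary
```

Half of the possible relationships were observed (`density = 0.5`); any
two individuals are at most two links apart (`D = 2`); `E2 = 0.75` says an
average dyad sits 1.33 links apart; `CI ≈ 93` flags a network almost as
centralised as a perfect star (ana mediates nearly everything); and
`Q = 0` means no division into subgroups beats the trivial partition.

A full synthetic cohort, its metrics and the comparative battery:

```r
cfg <- cohort_config(seed = 42)          # 78 groups, 24 species, 6 families
coh <- generate_cohort(cfg)
tab <- cohort_table(coh$metadata, cohort_metrics(coh$networks))
rep <- run_paper_battery(tab, coh$tree, n_perm = 999, seed = 42)
rep
#> <battery_report> 78 groups, 4 models (reml), 14 ledger rows, 5 variance tests
#>   E1: K = 0.255, P = 0.722
#>   E2: K = 0.433, P = 0.155
rep$models$E2.all$coefficients
#>              term estimate       se    ci_lo    ci_hi        p
#> 1     (Intercept)  1.14672 0.052029  1.04474  1.24869 5.44e-34
#> 2  log_group_size -0.12949 0.013609 -0.15616 -0.10281 2.03e-14
#> 3       sex_ratio  0.01127 0.040380 -0.06787  0.09041 7.81e-01
#> 4 neocortex_ratio -0.00176 0.009771 -0.02091  0.01740 8.58e-01
#> 5              CI -0.00323 0.000376 -0.00396 -0.00249 1.11e-12
```

The fit recovers the structure the generator plants: dyadic efficiency
falls with group size and with centralisation, while sex ratio (the
built-in negative control) shows no effect; the K values report no strong
phylogenetic signal in either efficiency for this cohort. The same stages
are available from the shell via `inst/scripts/primatenet`
(`generate` / `metrics` / `stats` / `all`; exit codes 0 = success,
1 = partial failure, 2 = input error).

## Package layout

- `R/network_io.R` — reading, validation, symmetrization and writing of
  association matrices, edge lists and cohort metadata.
- `R/metrics.R` — all per-group network statistics.
- `R/synthetic_data.R` — taxonomy + tree + cohort generator with
  controllable centralisation and modularity.
- `R/correlations.R`, `R/variance_tests.R`, `R/phylo_signal.R`,
  `R/mixed_models.R`, `R/battery.R` — the comparative statistics.
- `R/pipeline.R`, `inst/scripts/primatenet` — pipeline stages and the
  command-line front end.
- `vignettes/network-efficiency.Rmd` — the methods vignette: model
  definitions, numerical choices, generator design, limitations.
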