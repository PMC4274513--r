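---
title: "Measuring and comparing the efficiency of primate social networks"
author: "primatenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and comparing the efficiency of primate social networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primatenet)
```

## The problem

Group-living animals move information — about food, predators, innovations —
through their social ties, and the structure of those ties determines how
fast and how completely information can spread. `primatenet` implements a
comparative workflow for asking whether species-level traits (relative
neocortex size, group size, social style) predict how *efficient* a group's
association network is. The unit of analysis is one group: a weighted,
symmetric association matrix built from socio-positive interactions (body
contact, grooming or proximity), one interaction class per group. A cohort
of such groups, spanning species nested in genera and families, is then the
input to hierarchical comparative models.

## The network statistics

For a group of $N$ individuals with $I$ connections (unordered pairs with
positive symmetrized weight), the package computes:

* **Edge density** $= I / \binom{N}{2}$: observed over possible
  relationships.
* **Diameter** $D$: the longest of the binary shortest paths (the fewest
  links needed to pass between the two most separated individuals).
* **Global Efficiency** $E_1 = N / (I \cdot D)$: high when many individuals
  are reachable through few connections; it measures transmission from a
  spreader to the periphery.
* **Average Dyadic Efficiency**
  $E_2 = \binom{N}{2}^{-1} \sum_{i<j} 1/d_{ij}$: the mean inverse shortest
  path length over all dyads, 1 exactly on a complete network.
* **Eigenvector centralities** $C_i$: the principal eigenvector of the
  weight matrix, normalized to unit Euclidean length; an individual is
  central when it is strongly associated to individuals who are themselves
  strongly associated.
* **Centralisation index**
  $CI = 100 \cdot \sum_i (C_{max} - C_i) \, / \, S^\*(N)$, where $S^\*(N)$
  is the same sum evaluated on an unweighted $N$-node star. A star scores
  100, any vertex-transitive network (complete graph, cycle) scores 0, and
  values above 100 flag networks fragmented into isolated clusters.
* **Maximum modularity** $Q$: the best found value of within-cluster weight
  fraction minus its expectation under the degree-sequence null.

### Numerical choices

*Shortest paths* default to **binary** hop counts on the graph of
positive-weight pairs; the phrase "fewest number of links" describes hop
counts even on weighted networks. A `weighted_inverse` mode (edge length
$1/w$, so strong bonds are short) is available for sensitivity analysis.

*Disconnected pairs* contribute $1/d = 0$ to $E_2$ (the Latora–Marchiori
convention), and the diameter is taken over connected pairs with a warning;
a network with no connected pair at all is an error.

*$E_1$ is not clipped.* Although efficiency indices are conventionally
described as ranging from 0 to 1, the raw formula $N/(I \cdot D)$ exceeds 1
on very small or sparse graphs (a 2-node network gives 2). The package
returns the raw value rather than guessing a hidden normalization.

*Eigenvector normalization.* The $C_i$ are scaled to unit Euclidean norm,
and $S^\*(N)$ is recomputed under the same normalization for every $N$, so
$CI$ is self-consistent whatever norm convention is used; the star
calibration ($CI = 100$ to $10^{-6}$) is the testable anchor. On fragmented
networks centralities are computed on the largest component (ties broken
toward the component containing the earliest node) with zeros elsewhere,
which is what pushes $CI$ above 100.

*Modularity optimizer.* Newman's leading-eigenvector method (deterministic,
via igraph) followed by an in-package single-node-move refinement pass that
greedily relocates nodes, scanning in index order until no move improves
$Q$. If no split beats the trivial one-cluster partition the trivial
partition ($Q = 0$) is returned, so reported $Q \in [0, 1]$. Communities
are renumbered in order of first appearance, giving equal-$Q$ partitions a
canonical representative. The test suite holds this optimizer to an exact
standard on small fixtures: on two 5-cliques joined by a bridge it must
match an exhaustive search over all bipartitions. We chose to keep the
exhaustive search as an independent test oracle rather than an `N <= 12`
code path inside the optimizer: a second in-package route would either
share code with the first or silently change results across the size
boundary, while an oracle in the tests keeps one behaviour for all sizes
and still pins it exactly where enumeration is feasible.

*Symmetrization* is the arithmetic mean of the two directed weights, which
preserves total interaction mass and is idempotent; max- or sum-rules would
inflate weights asymmetrically. An unordered pair counts toward $I$ iff its
symmetrized weight is strictly positive, and blank cells in adjacency files
are read as 0: in association data, absence of observation is absence of an
edge.

All floating-point assertions in the test suite use absolute tolerance
$10^{-6}$ unless the property is exact by construction.

## The synthetic cohort generator

Real multi-group association datasets are scattered across supplementary
materials and archives; the package therefore ships a generator that
emulates the *composition* of a typical comparative cohort so every
downstream stage is testable end to end. Defaults: 78 groups from 24
species in 15 genera and 6 families, group sizes 5–40, captive:wild context
in roughly the 33:41 proportion, with the 4 groups of the largest-neocortex
species flagged as the outlier subset (emulating the human groups such
datasets contain; their context is `not_applicable`).

Each group's network is drawn from a two-knob family
(`generate_network()`): edge probabilities interpolate between an exact
star (`ci_target` $\to$ 1) and a dense Erdős–Rényi topology (`ci_target`
$\to$ 0), then a planted partition of 2–4 blocks multiplies between-block
probabilities by $(1 - q\_target)$. Weights are lognormal (meanlog 0,
sdlog 0.5) — a modelling placeholder, not a claim about real association
weights, which the comparative literature does not characterise
distributionally. A hub-anchored spanning backbone guarantees
connectivity. The star–dense interpolation was chosen over preferential
attachment because its $CI$ endpoints are analytically known (100 and near
0), making calibration testable.

Planted covariate effects act **through the knobs**, never by overwriting
computed metrics:

* the dense-endpoint probability follows
  $\operatorname{logit}^{-1}(2.6 + \beta_{\log N} \log N)$ with
  $\beta_{\log N} = -0.8$ by default, so larger groups are sparser and
  mechanically less globally efficient;
* `ci_target` follows
  $\operatorname{logit}^{-1}(\operatorname{logit}(0.35) +
  \beta_{neo}(\text{neo} - \bar{\text{neo}}) + u)$ with
  $\beta_{neo} = 0.25$ and a group-level spread $u$ whose amplitude is
  scaled by $|\beta_{CI}|$; the spread generates the centralisation
  variation that induces the negative $E_2$–$CI$ relationship;
* `q_target` is uniform on $[0.05, 0.95]$, which yields the positive
  $Q$–$CI$ coupling seen in real cohorts (both knobs sparsify).

`noise_sd` (default 0.15) adds Gaussian noise to both knob equations; at 0
the knobs are a deterministic function of the covariates, which is the
configuration used for sign-recovery tests. Neocortex ratios are simulated
by Brownian motion on the generated tree and mapped affinely into
[1.5, 4.2] (bracketing published strepsirrhine-to-human values), so they
carry genuine phylogenetic autocorrelation; per-species values from the
literature are deliberately not reproduced. Sex ratio is uniform on
[0.2, 0.8] and never enters the knob equations — it serves as a built-in
negative control.

The taxonomy is sampled by distributing species over genera and genera
over families (each parent non-empty), and the tree by nested random
coalescence — species join within their genus at depths 0.05–0.35, genera
within their family at 0.40–0.65, families at 0.70–1.00 on a unit-depth
scale — so the tree is ultrametric and agrees with the taxonomy by
construction. One global seed fans out to per-group seeds by a stable
string hash of the group id, so adding or reordering groups never changes
the networks of the others.

**What passing tests do and do not show.** The generator reproduces the
cohort's *structure* (nesting, size ranges, metric coverage: the default
cohort contains groups with $CI > 60$ and $< 30$, $Q > 0.4$ and $< 0.1$)
and carries known effect directions, so it can certify that the pipeline
recovers planted signals. It does not reproduce any real group, species
identity or weight distribution, so passing tests say nothing about the
effect sizes in real primate data.

## The comparative statistics

`run_paper_battery()` orchestrates the full analysis on a cohort table
(the join of metadata and metrics):

* **Hierarchical models** for each efficiency response ($E_1$, $E_2$) on
  log group size, sex ratio, neocortex ratio and $CI$, with nested random
  intercepts for family and genus-within-family, fit on the full cohort
  and on the cohort with flagged groups removed. Two inference routes:
  `reml` (lme4, Satterthwaite p-values) and `bayesian_mcmc` (JAGS; diffuse
  normal priors on slopes, half-Cauchy scale 2.5 on standard deviations —
  the original analyses name no priors, so a prior-free REML cross-check
  is the default and the test suite requires the two routes to agree on
  fixed-effect signs). Bayesian "p" is twice the smaller posterior tail
  probability, floored at $2/m$ draws, for comparability of report
  columns. Variance components are reported as proportions of the total
  (family, genus, residual), the quantity used to describe taxonomic
  signal in efficiency.
* **Correlation ledger**: the battery's Pearson and first-order partial
  correlations (e.g. $Q$–$CI$, $Q$–$CI$ controlling density,
  $E_1$–group size controlling $CI$ or density), corrected by the Holm
  step-down sequential Bonferroni procedure: the $k$-th smallest p is
  compared to $\alpha/(m-k+1)$ and rejection stops at the first failure.
  Partial correlations use the closed first-order formula; the tests
  verify it against the residual-regression route to $10^{-10}$.
* **Variance-homogeneity tests** of each efficiency across context
  (captive vs wild) and interaction type (contact vs proximity), plus
  $CI$ across context. The original analyses report an unnamed variance
  test with df $(1, n-2)$; we implement the Brown–Forsythe/Levene test
  (one-way ANOVA on absolute deviations from group medians), the robust
  standard whose df pattern matches. It is slightly conservative below
  roughly 20 observations per group — null calibration is exact by
  $n = 30$ per group — and never anti-conservative in our checks.
* **Blomberg's K** for the species means of both efficiencies, with a
  tip-permutation test. $K$ compares observed trait variance structure to
  the Brownian expectation on the tree ($K \approx 1$ under BM,
  $K \approx 0$ for no signal), is affine-invariant, and its p-value is
  the proportion of permutations whose tree-aware MSE is at most the
  observed one, with the observed arrangement counted:
  $p = (1+b)/(m+1)$, never zero. The tree's branch lengths are used as
  generated (unit-depth scale); $K$ is scale-free so the depth unit is
  immaterial.

## Problem sizes used in the checks

The shipped test suite and acceptance script run entirely on generated
data at the package's default cohort size (78 groups): oracle equivalence
on 20 random graphs of up to 12 nodes (where Floyd–Warshall and exhaustive
bipartition enumeration are exact), 200-network batches for the modularity
bound, 20 noiseless cohorts for slope-sign recovery, 200 Brownian
replicates for the $K \approx 1$ calibration, and 199–999 permutations for
p-values. These sizes give stable Monte-Carlo margins for every asserted
band while keeping a full run in a few minutes.

## Known limitations

* The centralisation index depends on the eigenvector normalization
  convention; the star calibration constrains but does not uniquely
  determine the convention used by legacy network software, so absolute
  $CI$ values from other tools may differ even though orderings agree.
* $E_1$'s printed range contradiction (see above) is resolved in favour of
  the raw formula; cross-study comparisons should use the same convention.
* The modularity optimizer is a heuristic; outside the enumerable regime
  its $Q$ is a lower bound on the true maximum.
* The generator's planted effects are directional, not calibrated to real
  effect sizes; power statements on synthetic cohorts do not transfer to
  field data.
* Phylogenetic non-independence is handled by taxonomic random effects
  plus a separate signal test, not by PGLS; this mirrors the comparative
  design the package implements rather than current best practice.
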