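---
title: "Co-activation networks and the DG microcircuit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-activation networks and the DG microcircuit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cofosnet)
```

This vignette is the package's account of its own methods: the statistical
models, the choices made where the design was genuinely open, the
synthetic-data generator that stands in for per-animal immunofluorescence
counts, and what the test suite does and does not establish.

## The co-activation network model

The unit of observation is an animal; the variables are c-Fos+ cell counts
per brain region, normalized within each group to percent of the group
mean, `(value / group mean) × 100`. Co-activation between two regions is
their Spearman correlation across the animals of one group. Spearman (on
average ranks, midranks for ties) is the right choice at n = 6–8 animals:
it is invariant to any monotone transformation of a region's counts, so
the log-normal marginal of the generator — or any other marginal — is
immaterial.

Two p-value routes are provided. The default is the t approximation
`t = ρ√((n−2)/(1−ρ²))` on `n − 2` degrees of freedom, chosen for
comparability with the common correlation packages. Because the
approximation is coarse at these sample sizes, an exact route enumerates
all `n!` orderings (feasible to n = 9) and reports the fraction of
permutations with `|ρ|` at least the observed. The network keeps an edge
iff `p < α` strictly (default 0.05), weighted by the signed ρ. **No
multiple-testing correction is applied across the region-pair matrix**;
this mirrors common practice in the c-Fos network literature and is the
single most important caveat when interpreting edge counts — at α = 0.05
a 24-region group contributes ≈ 14 spurious edges in expectation under
independence.

Constant regions (zero rank variance) have undefined correlations; their
pairs are recorded as missing and excluded from both the edge set and the
possible-pair count, never silently treated as zero, because a fake zero
would distort the edge-proportion comparisons.

### Sign convention for metrics

Negative correlations are biologically meaningful (they appear
predominantly in the mixed and high-similarity conditions) and are kept in
the data model, but all distance- and modularity-based computations use
`|ρ|`: node strength is `Σ|ρ|` (a signed sum would let negative edges
cancel positive ones and break the reading of strength as centrality), and
path lengths are `1/|ρ|`, which keeps every inverse distance at most 1 and
global efficiency inside [0, 1]. The alternative length `1 − |ρ|` was
rejected because it makes efficiency unbounded relative to the conventional
normalization. Signs re-enter only in `edge_composition()` and in the
excitatory/inhibitory interpretation of the microcircuit model.

### Louvain modularity and resolution selection

Louvain is greedy and order-dependent, so `louvain_partition()` shuffles
the node order under a seed; identical seed, identical partition. The
resolution parameter scales the null expectation in the quality function,
but the reported Q is always evaluated at resolution 1 on the final
assignment, so Q values are comparable across resolutions and groups. The
resolution itself is selected by stability: for each candidate, the
network is rebuilt on B animal-resampled bootstrap tables (resampling the
biological replicate — the animal — is the only defensible unit), Louvain
is run, and the number of modules among connected regions is recorded; the
winning resolution is the one whose modal module count recurs most often,
ties broken toward 1. Module counts exclude isolated regions, since a
region with no significant edges says nothing about community structure.

### The shuffle null and hub verification

The chance reference shuffles the off-diagonal structure of the
correlation matrix while keeping the main diagonal intact: the observed
upper-triangle (ρ, p) pairs are placed at uniformly permuted pair
positions and mirrored. Every member is symmetric, has the source's
diagonal, and carries exactly the source's off-diagonal value multiset;
because p-values travel with their correlations, thresholding a member at
the same α preserves the observed edge count while decoupling which
regions the edges join. This is the property the normalization needs: the
null randomizes *wiring* at fixed density and weight distribution, so
`raw / mean(null)` ≈ 1 for unstructured data and > 1 for genuinely
clustered data. (A simultaneous row-and-column permutation would merely
relabel the graph and leave every label-invariant metric unchanged —
useless as a reference.) A ring-lattice reference with matched node and
edge counts, largest weights on shortest ring distances, is reported
alongside as the high-clustering anchor.

Hub detection composes two rules conjunctively: a candidate must sit at or
above the 90th percentile of the observed network's node distribution on
at least one of degree, strength, or betweenness; a hub is a candidate
whose flagged metric also exceeds the 95th percentile of the shuffle-null
distribution of that metric. The null distribution is pooled across
regions: under the shuffle, node labels are exchangeable (every label
receives uniformly random wiring), so all regions share one null law, and
pooling estimates it from `n × B` values instead of B — the per-label
alternative is unstable precisely for planted hubs, whose own values
re-enter their label's null in roughly `B/n` members. The conjunction is
the conservative reading of a percentile rule plus an above-chance
verification; with homogeneous networks (everyone at the same percentile)
the null check is what prevents wholesale false positives.

### Group comparisons

Global metrics are compared by label permutation: animals pooled, group
labels permuted B times preserving group sizes, both networks rebuilt per
permutation, two-tailed p from the add-one estimator
`(1 + #{|null| ≥ |obs|})/(B + 1)` (never exactly zero at finite B).
Permutation was chosen over resampling for the hypothesis test because it
gives an exact test of group exchangeability at these sample sizes;
animal bootstrap is reserved for stability questions (resolution
selection). A caveat established by simulation during development: at 8
animals per group the permutation null keeps a fat tail from label splits
close to the original assignment (7+1, 6+2), so power at α = 0.05 caps
near 0.75 for *any* effect size; the test is calibrated (type-I rate
verified at ~0.05) but granular.

Edge proportions are compared on the groups × {edge, non-edge}
contingency table: an omnibus chi-square, then pairwise 2×2 chi-squares
Bonferroni-corrected over the number of group pairs; a continuity-corrected
variant is used (with a warning) when any expected cell falls below 1.

## The Bayesian microcircuit path model

The dentate-gyrus model is a fully observed recursive linear-Gaussian
system on (MC, PV_H, PV_GL, GC) — activated hilar cells (putative mossy
cells), activated PV+ interneurons in hilus and granule cell layer, and
activated granule cells:

```
PV_H  ~ Normal(0, σ_PVH²)            (exogenous scale)
MC    = a1·PV_H + e1
PV_GL = a2·MC + e2
GC    = b1·MC + b2·PV_GL + b3·PV_H + e3
```

Model 1 is this full system; model 2 keeps only the GC regression with MC,
PV_GL, PV_H as exogenous predictors (the "direct effects only"
comparison model; the alternative reading — the full system with the
indirect products simply not computed — has an identical likelihood to
model 1 and would make the information-criteria comparison vacuous, which
is why the single-regression reading was adopted). The likelihood
factorizes into regressions, but the joint posterior over all coefficients
and residual scales is the contract; sampling is by JAGS with four chains
and fixed per-chain RNG seeds.

Choices the source methods left open, fixed here and recorded in every
fit object:

* **Priors**: normal(0, 10) on path coefficients; half-normal(5) on
  residual scales. Both weakly informative on (near-)standardized data.
* **Scaling**: variables are centered before fitting (the system carries
  no intercepts); with `standardize = TRUE` (default) they are scaled to
  unit SD per fitted group, so sampled coefficients are standardized
  betas. Raw-scale fits (`standardize = FALSE`) are standardized after the
  fact by `sd(predictor)/sd(outcome)`; the two routes agree and the suite
  checks invariance to rescaling any variable.
* **Mediation quantities**: indirect effects are products of component
  draws, formed draw by draw (an exact identity asserted in the tests, not
  an approximation): `MC→PV_GL→GC = a2·b2`, `PV_H→MC→GC = a1·b1`; totals
  are `b1 + a2·b2` and `b3 + a1·b1`. Whether the three-path chain
  `a1·a2·b2` belongs in the PV_H total is ambiguous in the source
  framework; it is computed and reported as its own row and *not* folded
  into the total.
* **Diagnostics**: split-chain R̂ (each chain halved, classical PSRF over
  the 2C half-chains). PPP uses the maximum-likelihood moment discrepancy
  `F(S, Σ(θ)) = log|Σ| + tr(SΣ⁻¹) − log|S| − p` between the sample
  covariance and the model-implied covariance, with replicates of the same
  n simulated from Σ(θ); for model 2 the exogenous block enters at its
  sample covariance. A covariance-based discrepancy detects violations of
  the implied-covariance structure (omitted paths) but is blind to
  misspecification invisible in second moments (e.g. an even-power
  nonlinearity with zero covariance); the stress test in the suite uses an
  omitted direct path for this reason.
* **Information criteria**: DIC in the posterior-mean-deviance form with
  `p_D = mean deviance − deviance at posterior mean`; WAIC from the
  pointwise log predictive density with the variance penalty; LOOIC by
  importance-sampling leave-one-out with truncated weights (normalized
  weights capped at `√S/S`), with a count of observations whose weights
  are dominated by single draws.
* **Multigroup**: the free version fits each group independently
  (within-group standardization); the restricted version shares the five
  path coefficients across groups with group-specific residual scales, in
  one joint sampler. Comparison is by total DIC. Group contrasts take the
  difference of standardized draws pairwise (truncated to a common draw
  count), flagging a parameter when the 95% credible interval of the
  difference excludes zero or a sign probability exceeds 0.95.

Release settings are 4 chains × (1000 warmup + 5000 draws); the test suite
runs 4 × (250 + 750), which the recovery simulations show is ample for
this conjugate-like posterior (R̂ < 1.01 throughout).

## The synthetic-data generator

The generator defines the study conditions under which everything is
tested; its defaults mirror the motivating experimental design: five
groups (NOR, DIST, 25%, 50%, 75% similarity) of 6–8 animals and ~24
regions spanning the rostral/medial/caudal-dorsal/caudal-ventral
hippocampus plus parahippocampal layers.

* **Activation tables**: regions belong to modules (default 3 contiguous
  blocks); each animal draws one latent standard-normal factor per module;
  a region's count is `baseline × exp(loading × factor + ε)`,
  `ε ~ N(0, noise_sd²)`. Counts are log-normal — positive, right-skewed,
  and irrelevant in marginal form to the rank-based pipeline; what matters
  is that within-module pairs share a factor, so their expected Spearman
  correlation increases in the loading (verified over a loading grid).
  Defaults: loading 0.8, noise SD 0.4 (within-module correlation ≈ 0.8,
  strong but not degenerate modules), baseline 100 cells — the raw count
  scale is documented as arbitrary since no per-region magnitudes are
  available to match and the pipeline normalizes and ranks anyway.
  Group differences are encoded as *loading multipliers*, not mean shifts,
  because the network stage consumes correlations; a mean shift would be
  invisible to it.
* **Microcircuit tables**: generated directly from the structural
  equations with chosen coefficients and unit default residuals, verified
  against an independently derived covariance algebra at n = 10,000.
* **Behavior**: total exploration per trial is log-normal around 30 s; the
  novel share is `0.5 + bias/2` plus Gaussian noise clipped to [0, 1], so
  expected D1 ≈ bias.

What passing tests on this generator do **not** show about real data: real
c-Fos counts have region-specific baselines and dispersions, animals drop
out non-randomly, anatomical neighbors share segmentation noise
(inflating local correlations), and group differences in means and in
connectivity co-occur. The generator emulates the correlational geometry
the analysis assumes, nothing more.

## Numerical choices and degenerate inputs

* Ties in counts use average ranks everywhere; exact-permutation p-values
  compare `|ρ|` with a 1e−12 slack so ties in the permutation distribution
  are counted, not dropped to floating-point luck.
* Zero-total-exploration trials yield a missing D1/D2 (not 0) and are
  excluded from inclusion decisions with a message; a silent 0 would bias
  the above-chance rule toward exclusion.
* Effect-size labels at a cutpoint close on the larger-effect side
  (`|δ| = 0.147` is "small", `g = 0.5` is "large").
* Edgeless networks: efficiency 0, every region its own module with Q = 0
  (warning), no hubs; networks without connected triplets report
  clustering 0 with a message.
* All stage seeds derive deterministically from one master seed
  (`stage-name + index` hashing), so any stage can be reproduced in
  isolation; no function touches the global RNG stream without restoring
  it.

## Problem sizes in the shipped tests

The suite validates: rank statistics against all-orderings enumeration
(50 vector pairs, n ≤ 7); graph metrics against Floyd–Warshall/triangle
enumeration (100 random graphs, ≤ 8 nodes); Louvain on planted two-module
graphs (100 seeds); null-ensemble invariants (10 sources × 100 members);
permutation-test calibration under the null (100 replicate pairs at
7 animals, 24 regions, B = 99); hub calibration (60 planted-hub seeds, 30
homogeneous-ring seeds); path-model recovery (100 replicates at n = 200,
4 × (250 + 750) sampling) with per-coefficient credible-interval coverage
and Monte-Carlo-mean bias; diagnostic calibration (60 replicates for
R̂/PPP, 60 for WAIC model preference at n = 100). These sizes are the
package's chosen balance between Monte-Carlo precision and a test suite
that completes in minutes.

## Known limitations

* Raw-p thresholding (no FDR) is faithful to field practice but
  anticonservative; edge counts should be compared between groups, not
  read as absolute connectivity.
* The permutation comparison is granular at n = 6–8 per group (power
  ceiling ≈ 0.75 at α = 0.05); reporting exact p-values alongside the
  binary decision is recommended.
* The covariance-based PPP does not detect misspecification that leaves
  second moments intact.
* LOOIC uses truncated importance sampling, not Pareto-smoothed
  importance sampling; for the small, well-behaved Gaussian regressions
  here the two agree (WAIC–LOOIC concordance is tested), but heavy-tailed
  cases would deserve the smoothed estimator.
* The model-2 reading ("direct effects only" as a single GC regression) is
  one of two defensible interpretations; the other collapses onto model 1.
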