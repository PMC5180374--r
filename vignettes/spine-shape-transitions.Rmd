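---
title: "Shape taxonomies and transition models for dendritic spines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape taxonomies and transition models for dendritic spines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinetax)
```

## The problem

Dendritic spines — the micron-scale protrusions that carry most
excitatory synapses — are conventionally sorted into named shape classes
(stubby, mushroom, thin, filopodia). That taxonomy is subjective, has no
agreed quantitative definition, and sits awkwardly on data in which spine
shapes form a continuum. `spinetax` implements an alternative workflow:

1. start from a table of 11 morphometric descriptors per spine, measured
   at two time points (`t0` before and `t1` after a stimulus);
2. if two populations (e.g. chemically potentiated vs control) come from
   different cultures, select balanced subpopulations by closest-pair
   matching so that systematic culture differences do not masquerade as
   treatment effects;
3. reduce the descriptors to two interpretable coordinates — a
   generalized *size* and a generalized *slenderness* — by split
   principal component analysis;
4. build an unsupervised shape taxonomy by clustering all spines from
   both populations and both time points in that plane (crisp
   average-linkage hierarchical clustering, or fuzzy c-means when
   graded memberships are wanted);
5. estimate a Markov *shape transition model*: a row-stochastic `k x k`
   matrix `T` with `T[n, m] = P(C_n -> C_m | C_n)`, the probability that
   a spine whose shape is in cluster `n` at `t0` is in cluster `m` at
   `t1`;
6. attach bootstrap standard errors to each transition probability, and
   compare two populations as whole models with bootstrap hypothesis
   tests.

## The transition model

Clustering assigns each spine `s` a membership vector
`w^i(s) = (w_1^i(s), ..., w_k^i(s))`, non-negative and summing to 1, at
each time point `i`. Reading memberships as probabilities, the law of
total probability predicts the `t1` memberships from the `t0`
memberships:

    w_pred[m] = sum_n T[n, m] * w0[n]

`estimate_qp()` finds the `T` minimizing the squared prediction error
`E = sum_s sum_m (w_pred(s)[m] - w1(s)[m])^2` subject to `T >= 0` and
unit row sums. Writing `G = W0'W0` and `M = W0'W1`, the objective is a
convex quadratic `tr(T'GT) - 2 tr(T'M)` and the feasible set a product
of simplices, so the problem is a standard quadratic program; it is
solved by an active-set method (via `pracma::quadprog`) on the stacked
columns of `T`, restricted to source clusters with positive `t0`
occupancy. Unoccupied source rows carry no information; they are set to
the uniform distribution and flagged (`empty_rows`), and comparisons
exclude them by default.

For one-hot (crisp) memberships the optimum has the closed form
implemented in `estimate_crisp()`: row `n` of `T` is the empirical
distribution of `t1` clusters among spines that started in cluster `n`.
The QP reproduces this closed form on crisp input, which is one of the
package's standing regression checks.

Three baselines calibrate the model's prediction error
(`baseline_model()`): *majority* (harden each row to its argmax),
*identity* (no transitions), and *random* (rows drawn from a flat
Dirichlet). Because all three are feasible points of the QP, the fitted
model can never have larger training error than any of them.
`cross_validate()` compares the models out of sample: spines are split
into folds as paired (`t0`, `t1`) units, the taxonomy is refit on the
training spines of each fold, and held-out spines enter through the
model's own assignment rule — first-nearest-neighbour lookup for crisp
models, the explicit membership formula for fuzzy ones — at `t0` (the
prediction input) and at `t1` (the reference the prediction is scored
against). Refitting the clustering inside each fold keeps the held-out
spines genuinely unseen by every stage of the model.

## Tunable parameters

* **`k` (cluster count)** and **`m` (fuzzifier, > 1)**. Chosen from the
  within-cluster sum of squares `WSS = sum_n sum_s w_n(s) ||s - c_n||^2`,
  where `c_n` is the membership-weighted mean of the data. `wss_scan()`
  computes the curve over a grid (`m` grid default `1.5, 2, 3, 4, 5`)
  and `knee_select()` automates the usual visual rule: pick the `k`
  where the curve bends the most. The bend is measured as the largest
  discrete second difference of `log WSS` — a scale-free criterion that
  matches the visual elbow; on the raw curve the second difference is
  dominated by the first large drop (roughly `WSS(1) - 2 WSS(2)`) and
  would flag `k = 2` on almost any data with real structure deeper than
  two clusters. For fuzzy scans the smallest `m` whose knee agrees with
  the next larger `m` on the grid is chosen. The curve is always returned for manual
  override, and every fitting function accepts explicit `k` and `m`.
* **Loading truncation (default 0.10)**. After split PCA, loadings with
  magnitude below 10% of the unit-norm component are set to zero and the
  component is renormalized, trading a little variance for a reduced
  feature that reads as a short formula. Renormalization keeps the
  truncated projections on the same scale as untruncated ones.
* **Matching scale**. The balanced selection measures spine similarity
  by normalized Euclidean distance at `t0`; each descriptor is scaled by
  the pooled (both populations) standard deviation, recorded in the
  result. A constant descriptor would make the distance undefined, so
  its scale is set to 1 with a warning.
* **Bootstrap replicates** `R` (default 1000 for standard errors and
  tests; scale down for exploration). The p-value uses the
  `(1 + #{null >= observed}) / (R + 1)` finite-sample form, so it is
  never exactly zero and is exact under exchangeability.
* **Edge filter (default 0.20)**. Transition graphs show only edges with
  probability above the threshold. An alternative reading — filtering by
  transported share of the source cluster's initial weight — is
  available via `filter_mode = "mass"`; the two agree for occupied
  source clusters.

## Statistical comparison of populations

Two statistics compare populations that share one taxonomy:

* **RDC** — the summed squared difference of per-cluster *relative
  weight changes* `c_n(G) = (sum_s w1 - sum_s w0) / sum_s w0`. It is
  sensitive to how the overall shape distribution shifts.
* **SMD** — the summed squared difference of the two transition
  matrices, cell by cell. It is sensitive to how spines move between
  shapes even when the marginal distributions barely change.

`bootstrap_test()` pools the two groups, redraws groups of the original
sizes with replacement, refits the taxonomy on the union of each drawn
pair (both time points), estimates one transition model per group and
recomputes the statistic. Refitting on the union gives the two
per-replicate models a common cluster space, so cells are comparable
without any label matching. Feature reduction is fitted once on the
pooled original groups: replicates resample existing spines, whose
reduced coordinates do not change. Both statistics can be computed from
the same replicate stream in one call.

`bootstrap_se()` instead keeps the original cluster space entirely fixed
and resamples spines to re-estimate `T` alone: its purpose is a
like-for-like error bar per cell, which would be meaningless if the
cells changed identity across replicates. The reported error is the
square root of the mean squared deviation from the original estimate, so
it lives on the probability scale (a value of 0.66 means the cell is
unusable).

## The synthetic generator

No public per-spine descriptor dataset with paired time points exists,
so validation runs on `generate_population()`: a 2-D latent shape space
(size, slenderness) with `k` Gaussian clusters, pure Markov-on-clusters
dynamics (`t1` position drawn around the destination centroid,
independent of the `t0` position given the clusters), and a linear map
from latent coordinates to the 11 positive descriptors plus Gaussian
noise. Defaults keep descriptor means in realistic micrometre-scale
ranges (length ~ 1.2 um, area ~ 0.7 um^2) and use a within-cluster
spread (0.6) at which neighbouring clusters touch, because real spine
morphometry is a continuum of shapes, not a well-separated mixture.
Well-separated settings (spread 0.25) are used where a validation
scenario requires unambiguous ground truth, e.g. recovering a planted
transition matrix. Descriptor values are floored at a small positive
constant; the number of floored cells is recorded on the table.

What the generator does **not** emulate: measurement error correlated
across descriptors of one spine (segmentation error affects length,
area and circumference jointly), heavy-tailed descriptor distributions
(real length/width ratios are strongly right-skewed), within-spine
temporal autocorrelation beyond the cluster transition, and unequal
cluster prevalences as extreme as real data's rare filopodia. Passing
tests on this generator therefore demonstrate correctness of the
estimators under the model's own assumptions, not robustness to every
feature of microscope data.

## Numerical choices

* PCA uses the covariance matrix (descriptors share comparable
  micrometre-scale units); a `correlation = TRUE` flag standardizes
  first. The sign of each component is fixed by making its
  largest-magnitude loading positive, so repeated fits are identical.
* Fuzzy c-means runs from k-means++ seedings, 5 restarts by default,
  keeping the best objective; convergence at relative objective change
  `1e-6`, cap 300 iterations (non-convergence warns and keeps the last
  iterate). A point coinciding with a centroid receives full membership
  there (the formula's continuous limit).
* The QP is solved to ~1e-8; a ridge of `1e-10` times the mean diagonal
  is added only if the occupancy Gram matrix is numerically singular.
  Solver output is cleaned of sub-tolerance negative entries and
  renormalized.
* Greedy matching sorts all cross-population pairs once and sweeps;
  ties in distance break by (id, id) lexicographic order, so the
  selection is deterministic. Nearest-neighbour assignment breaks ties
  toward the smallest training index.
* All bootstrap and cross-validation randomness derives from one master
  seed through a fixed seed stream whose prefix is stable, so
  increasing `R` does not perturb earlier replicates.
* Cross-population distances are accumulated descriptor by descriptor
  rather than via the Gram identity, so identical spines are at exactly
  zero distance.

## Known limitations

* **WSS monotonicity at large fuzzifiers.** The WSS with plain
  membership weights is bounded above by its `k = 1` value, and
  decreases monotonically along `m` (softer memberships always raise
  it). Along `k`, monotonicity is guaranteed for the crisp hierarchical
  curve (cutting the tree refines the partition), but not for fuzzy
  c-means at large `m`: in the flat tail of the curve the best
  attainable fit at `k + 1` clusters can have a marginally (~0.1-0.5%)
  *higher* plain-weight WSS than at `k`, because the algorithm
  optimizes its own `w^m`-weighted objective, not the WSS. `wss_scan()`
  mitigates this by selecting restarts on the scanned quantity and by
  warm-starting each `k` from the previous solution, but small
  non-monotonicities can survive; they never affect the knee, which
  lives in the steep part of the curve.
* Balanced matching is greedy, not optimal-assignment; with 400 spines
  per group it can remove moderate systematic differences (~0.3 pooled
  SD per descriptor) when 300 pairs are drawn, but no 25% trimming can
  neutralize shifts of a full pooled SD — the worst-descriptor p-value
  then improves without clearing conventional significance.
* The transition model is first-order Markov on cluster labels between
  exactly two time points; longer imaging series would need a chain of
  models and are out of scope.
* The two comparison statistics are reported without multiplicity
  correction, mirroring how such model comparisons are usually read.

## Validation problem sizes

The shipped tests validate estimators at sizes chosen to make ground
truth sharp while keeping the default suite quick: transition recovery
on 2000 spines with three well-separated latent clusters (max
elementwise error below 0.05); QP/crisp agreement on 50 random one-hot
instances (to 1e-6); test size under the null from 200 trials of
pooled-resampling with `R = 199` at nominal level 0.05; and balanced
matching on 400-spine groups with a 0.3-SD systematic latent shift.
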