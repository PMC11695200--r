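---
title: "Methods: dynamic connectivity, brain states, and multilayer switching in dynfnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic connectivity, brain states, and multilayer switching in dynfnc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dynfnc` implements the analysis layer that sits downstream of group spatial
ICA in resting-state connectomics studies of age-related hearing loss and
similar case-control designs. Its inputs are per-subject time-by-channel
matrices — summary time courses of selected independent components organized
into functional networks (DMN, CEN, SN, AUN, VN, SMN), and optionally
atlas-node time courses for whole-brain analyses — plus a subject manifest
carrying group membership and covariates (age, gender, education, mean
framewise displacement, clinical scores). This document describes the models
and procedures, the tunable parameters, the synthetic-data generator used
for validation, and the numerical choices made where the design was open.

## Static and dynamic connectivity

Static functional network connectivity (`sfnc()`) is the Pearson correlation
between every channel pair over the full scan, Fisher-z transformed
(`z = atanh(r)`). Correlations with `|r| >= 1 - 1e-7` are clipped before the
transform so degenerate pairs stay finite; the bias introduced by the clip is
negligible (`atanh(1 - 1e-7)` is about 8.4). The diagonal is stored as zero
because all downstream feature extraction uses the strict lower triangle,
vectorized in row-major order `(2,1), (3,1), (3,2), ...` — a convention fixed
across every module.

Dynamic connectivity (`dfnc()`) uses a tapered sliding window: a rectangle of
`width` volumes (default 20 TR, i.e. 40 s at TR = 2 s) convolved with a
truncated discrete Gaussian (`sigma` = 3 TR, cut at three sigma), advanced in
steps of 1 TR. The taper is the central `width` samples of the full
convolution, renormalized to sum to one. Within each window, correlations use
taper-weighted means and covariances — this is what the Gaussian convolution
means operationally, rather than slicing followed by unweighted correlation.
The window count is exactly `W = floor((T - width)/step) + 1`; 234 retained
volumes at the default geometry give 215 windows. A channel that is constant
inside a window yields zero correlations for its pairs, with a warning.

## Brain states and temporal metrics

Windowed z-vectors from all subjects are pooled and clustered into `k`
recurring connectivity states (`cluster_states()`, default `k = 6`).
The optimizer is Lloyd-style k-means with k-means++ seeding and a
best-of-`n_restarts` (default 20) rule. City-block distance with
per-coordinate median centroids is the default, matching common dFNC toolbox
practice; squared-Euclidean with mean centroids is available. Empty clusters
are re-seeded at the point farthest from its current centroid. k-means++
seeding matters in this application: connectivity states are strongly
imbalanced in occupancy, and plain random-point initialization can merge two
small states and split a large one into a local optimum that survives twenty
restarts. State indices are deterministic: states are renumbered by
descending pooled occurrence.

Per subject, `state_metrics()` reports fraction time (share of windows per
state), mean dwell time (average maximal-run length in windows, `NA` for
unvisited states), and the number of adjacent-window transitions.
Connectivity variability (`dfnc_variability()`) is the across-window sample
standard deviation (denominator `W - 1`) of the windowed correlation
coefficients `r` — deliberately on the `r` scale, not the z scale, following
the definition of connectivity-strength variability.

## Windowed graph topology

For each window, the correlation matrix is binarized over a sparsity grid
(`threshold_by_sparsity()`): the top `round(s * C(C-1)/2)` edges by signed
weight are retained (anticorrelations drop first; absolute-value ranking is
available), ties broken lexicographically. Global efficiency is the mean
inverse shortest-path length over ordered pairs (disconnected pairs
contribute zero); local efficiency is the mean over nodes of the global
efficiency of each node's neighbor-induced subgraph (zero below degree 2).
Shortest paths are computed by boolean matrix-power BFS, which at the call
volumes of the flexibility stage (every window times every sparsity) is far
cheaper than constructing graph objects per call; the implementation is
checked against a literal queue BFS and against igraph in the tests.
`efficiency_flexibility()` integrates each metric over the sparsity grid by
the trapezoid rule (one AUC per window; a single grid point degenerates to
the metric itself) and reports the across-window standard deviation. The
default grid 0.10–0.34 in steps of 0.01 keeps mean degree above `log(C)` at
the low end for 13-node networks. Integrating before taking the SD (rather
than the reverse order) yields one topology number per window, which is what
"variability of a topological metric" denotes; the alternative ordering can
be emulated by passing single-point grids.

## Multilayer modularity and network switching

The multilayer stage treats a subject's time-ordered windowed networks
(nonnegative weights; negative correlations zeroed by default) as layers of
one network. The quality of a community assignment `g` over (node, layer)
units is

Q = (1/2mu) * sum_{ijlr} [ (A_ijl - gamma * k_il * k_jl / (2 m_l)) delta_lr
    + delta_ij * omega * 1{|l - r| = 1} ] * delta(g_il, g_jr)

with uniform resolution `gamma` (default 1.1), ordinal interlayer coupling
`omega` (default 0.5) connecting each node to its own copies in adjacent
layers only, per-layer strengths `k` and total weights `2 m_l`, and `2 mu`
the total intra-layer weight plus total coupling. A layer with zero total
weight contributes a zero null term (with a warning).

`louvain_multilayer()` optimizes Q by greedy moves over (node, layer) units —
candidate communities are those of intra-layer neighbors and of the node's
adjacent-layer copies, with the null-model term handled implicitly — and, on
convergence of a pass, by moves on the community-collapsed quality matrix,
iterating both phases to a local optimum. Visiting order is randomized from
the seed and the best of `n_repeats` restarts (by Q, re-evaluated
independently by `multilayer_modularity()`) is returned. Labels are
canonicalized in first-occurrence order. On all-partition enumerations of
4-node/2-layer instances the optimizer attains the exhaustive optimum in at
least 95% of random instances.

The network switching rate of a node is the fraction of adjacent-layer
transitions at which its community label changes, in [0, 1]. Because the
optimizer is stochastic, `consensus_switching()` reports the mean rate over
`n_repeats` independent runs with derived seeds, together with the
across-run SD. At `omega = 0` the quality decouples: the unnormalized Q
equals the sum of unnormalized per-layer modularities at the same partition
(the normalized values differ because `2 mu` is a whole-stack constant). At
very large `omega` the coupling dominates and every node keeps one community
across all layers, so switching is identically zero.

## Inference layer

Group contrasts on any per-subject feature (static pairs, state-wise
connectivity, temporal metrics, variability, flexibility, switching rates)
use an OLS GLM on intercept + group + covariates (age, gender, education by
default; mean FD appended for the head-motion validation pass), reporting the
group coefficient, its t statistic with `n - p` degrees of freedom, and a
two-sided p value. Without covariates this reduces exactly to the pooled
two-sample t test. Benjamini–Hochberg adjustment (via `stats::p.adjust`)
is applied per feature family at `q < 0.05`; the temporal state properties
are conventionally reported uncorrected, which `group_glm(fdr = FALSE)`
provides. Associations with clinical traits use partial correlations:
Pearson correlation of OLS residuals after the covariates, with
`df = n - 2 - #covariates`. Subgroup contrasts within the patient group
split at MoCA >= 26 or age >= 60 and reuse the same machinery. The
demographic table tests are reproduced directly from per-group mean/SD/n
summaries (Welch or pooled t, chosen per row by which formula reproduces the
printed statistic) and a Pearson chi-square without continuity correction
for the gender table.

## The synthetic cohort generator

No raw data accompany the study design this package targets, so validation
rests on a generative model that captures what the analysis assumes: recurring
covariance states with Markov dynamics. `make_cohort()` draws, per subject, a
state sequence from a sticky transition matrix (default self-transition 0.97,
mean dwell around 30 volumes, consistent with dominant-state occupancies
reported for resting-state cohorts) and emits zero-mean multivariate normal
observations with the active state's covariance. The default state library
(`state_covariance_library()`) builds six states from one-factor loading
patterns over the six networks — each state couples a pair of networks
positively and one negatively — plus a diffuse weak-connectivity state
mimicking the typically dominant weakly coupled state. Group effects are
injected as Fisher-z shifts on configured pairs with covariance
reconstruction (eigenvalue clipping at 1e-6 restores positive definiteness
when needed); defaults weaken the within-DMN pair and strengthen DMN–SN and
DMN–VN pairs in the patient group, the directions reported for hearing-loss
cohorts. Covariates mirror typical case-control margins: age ~ N(58.6, 6.7)
truncated to [50, 80], education ~ N(10.9, 1.7), gender ~ Bernoulli(0.525),
mean FD ~ N(0.23, 0.07) truncated at zero, plus MoCA and mean-PTA style
scores for the correlation and subgroup machinery. Per-subject random
streams derive from (master seed, subject index), so cohorts are
reproducible under reordering. Node-level series for the multilayer stage
share each subject's state sequence, with network-level loadings expanded to
the nodes.

What the generator does *not* emulate: hemodynamics, scanner noise, head
motion, ICA mixing or back-reconstruction, spatial structure of any kind,
and non-Markov temporal structure. Passing recovery tests therefore
demonstrates correctness of the estimators under the model the analysis
itself presumes — not robustness to the full physics of fMRI.

### The state-recovery benchmark

The recovery benchmark used by the tests and the acceptance script runs 20
subjects at T = 234 with six *all-pattern* states (`include_weak = FALSE`,
loading strength 0.85) and a sticky chain (self-transition 0.99 — sticky
enough that transition-straddling windows are rare, while every state keeps
enough occupancy to be identifiable; much stickier chains let single states
nearly vanish from a 20-subject cohort). Two
deliberate choices need explanation. First, windows that straddle a state
transition have no well-defined generative label — the windowed covariance is
a genuine mixture — so recovery is scored on windows whose dominant state
carries at least 75% of the taper mass; the truth label of a window is the
state with the largest taper-weight mass (`true_window_states()`). Second,
the diffuse weak state is excluded from the benchmark library because
mixtures of two opposing strong patterns pass near its centroid, so
transition windows and short noisy runs would be attracted to it — a property
of the scenario, not an estimator error. Under this benchmark the
decomposition recovers states essentially exactly (ARI above 0.99,
fraction-time error below 0.05 across seeds); with the realistic cohort defaults (weak state present,
shorter dwells) ARI is around 0.85–0.9, the loss being attributable to
transition-window ambiguity. The separation requirement is checked as a
ratio: minimum inter-centroid distance in pair-z space at least five times
the per-coordinate within-state spread of windowed estimates (about 0.27 at
the default window geometry).

## Parameters at a glance

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `window$width` | 20 | TR | 40 s at TR = 2 s |
| `window$sigma` | 3 | TR | Gaussian taper; `1e-6` ~ uniform |
| `window$step` | 1 | TR | window advance |
| `states$k` | 6 | — | number of connectivity states |
| `states$metric` | city-block | — | median centroids; `euclidean` available |
| `states$restarts` | 20 | — | k-means++ restarts |
| `topology$sparsity_*` | 0.10–0.34, 0.01 | proportion | binarization grid |
| `multilayer$gamma` | 1.1 | — | intra-layer resolution |
| `multilayer$omega` | 0.5 | — | ordinal interlayer coupling |
| `multilayer$repeats` | 20 | — | optimizer restarts / consensus runs |
| `stats$fdr_q` | 0.05 | — | BH threshold |

## Numerical choices and degenerate inputs

- Correlation clipping at `1 - 1e-7` before `atanh`; `fisher_z` errors on
  non-finite input.
- Edge-count rounding in thresholding uses deterministic half-up rounding;
  ranking ties break by (i, j) pair order.
- k-means ties in assignment go to the lowest-index centroid; the final
  assignment is a fixpoint (each centroid equals its cluster's
  mean/median within 1e-8).
- Louvain moves require a strict gain above 1e-12; ties keep the current
  community, making runs deterministic given the seed.
- Zero-weight layers: null term defined as zero, warning emitted.
- Rank-deficient GLM designs error with the names of collinear columns; a
  zero-residual outcome reports effect 0 with p = 1 by convention.
- The sequence length, window count, and state-label conventions are exact
  (no silent truncation); the reference geometry note — published pipelines
  sometimes report round window counts such as 200 — is not reproduced
  because no truncation rule is defined; the formula value (215 windows for
  T = 234) is used throughout.

## Problem sizes used in validation

The shipped tests and the acceptance script run: five 20-subject recovery
cohorts at T = 234 (about 4,300 pooled windows each); ten planted-partition
layered networks of 20 nodes by 10 layers with 10-run consensus switching;
50 random graphs of up to 12 nodes against the BFS oracle; 20 exhaustive
4-node/2-layer modularity enumerations (2,795 partitions each); 200 null
GLM simulations; 1,000 random p-vectors against the brute-force BH rule;
and 20 repeats of a 30-vs-30 cohort with a 0.3 z-shift on one pair. A
10+10-subject end-to-end pipeline smoke test runs at T = 60 with 8 nodes.

## Known limitations

- The multilayer optimizer is a greedy local search; on large node-by-layer
  stacks it finds good local optima, not certified global ones. Consensus
  over repeats is the intended usage.
- City-block k-medians uses coordinate-wise medians; with very few windows
  per cluster the median is sensitive to ties.
- The generator's Gaussian emissions cannot produce heavy-tailed artifacts;
  FDR calibration under strong non-Gaussianity is untested.
- Weighted-graph efficiencies, categorical (all-to-all) interlayer coupling,
  meta-state analyses and time-frequency dFNC are out of scope.
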