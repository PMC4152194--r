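---
title: "Methods: signed functional-connectivity networks, modularity, hubs and reproducibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed functional-connectivity networks, modularity, hubs and reproducibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signedfc)
```

## Overview

`signedfc` analyses resting-state brain activity as a *fully connected,
signed, weighted network*: nodes are anatomically defined regions of
interest (ROIs), and the edge between two regions carries the Fisher
z-transformed *partial* correlation of their time courses — the
association that remains after conditioning on every other region, often
read as "direct" functional connectivity. Because partial correlations can
be negative, the network has both positive and negative weights, and every
downstream statistic (modularity, strength, diversity) is a generalization
that treats the two sign layers separately and recombines them with
negative connections in an auxiliary role.

The pipeline is: per-subject ROI time series → per-subject partial
correlation matrix → Fisher z → cohort/group averaging → signed modularity
partitioning → hub classification → reproducibility statistics (mutual
information and variation of information between partitions, against
permutation null networks).

## Connectivity model

For a subject with time-series matrix $X \in \mathbb{R}^{T \times N}$
(here $T = 165 > N = 36$), the partial correlation between regions $i$ and
$j$ is computed from the precision matrix $\Omega = R^{-1}$ of the sample
*correlation* matrix $R$:

$$\mathrm{pcorr}(i,j) = -\frac{\Omega_{ij}}{\sqrt{\Omega_{ii}\,\Omega_{jj}}}.$$

Working with $R$ rather than the covariance makes the estimate invariant
to per-region signal amplitude; the partial correlations themselves are
identical either way, but the inversion is better conditioned. A singular
or near-singular $R$ (condition number above $10^{12}$) is an error unless
shrinkage is enabled: `partial_correlation(ts, shrinkage = TRUE)` shrinks
$R$ toward the identity with a Schäfer–Strimmer-style analytic intensity,
which keeps the estimator defined for user data with $T \le N$. The
default design does not need it, so shrinkage defaults off.

Correlations are mapped to Fisher z ($z = \operatorname{artanh} r$, inputs
clipped at $|r| = 1 - 10^{-7}$) *before* any averaging, and all averaging
is element-wise on the z scale. Matrix diagonals are stored as zero and
excluded from every graph sum; self-connections are never used. A
fully-connected network on $N = 36$ regions therefore has
$\binom{36}{2} = 630$ edges.

## Signed modularity

A partition $M$ assigns each node a module. Each sign layer
($w^{+} = \max(w, 0)$, $w^{-} = \max(-w, 0)$) is scored with standard
weighted modularity,

$$Q^{\pm} = \frac{1}{v^{\pm}} \sum_{ij}
  \left(w^{\pm}_{ij} - \gamma\,\frac{s^{\pm}_i s^{\pm}_j}{v^{\pm}}\right)
  \delta(M_i, M_j),$$

with node strengths $s^{\pm}_i = \sum_j w^{\pm}_{ij}$, totals
$v^{\pm} = \sum_{ij} w^{\pm}_{ij}$ (double-counting convention: twice the
upper-triangular sum), and sums over all ordered pairs of the
zero-diagonal weight matrix — the matrix convention of standard weighted
modularity, under which the single all-encompassing module on an
all-positive network scores exactly zero. The combined index is

$$Q^{*} = Q^{+} - \frac{v^{-}}{v^{+} + v^{-}}\,Q^{-},$$

so negative weights influence the partition but can never outvote positive
ones (their term is scaled by the negative share of total weight). A
symmetric alternative $Q^{+} - Q^{-}$ is available via
`negative_weighting = "symmetric"`. If the network has no negative
weights, $Q^{*} = Q^{+}$ exactly; an all-negative network degenerates to
$Q^{*} = -Q^{-}$. The resolution parameter $\gamma$ defaults to 1 and is
exposed for sensitivity analysis only.

`maximize_modularity()` is a Louvain-type greedy optimizer adapted to the
signed objective: single-node moves are accepted when they increase
$Q^{*}$ (computed jointly from both layers), modules are agglomerated into
super-nodes (self-loops carry internal weight), and the two phases repeat
until no gain remains. Determinism and robustness choices:

* each restart scans nodes in a seeded random order, and ties break at the
  first maximal gain in scan order, so a (network, seed) pair always gives
  the same result;
* every restart's solution is refined by single-node moves on the original
  (un-agglomerated) network, which repairs coarse moves made at
  aggregated levels;
* the single-module and all-singleton partitions are always scored as
  baselines, so the returned partition is never worse than either;
* the returned `q_star` is re-derived by `modularity_score()` on the
  returned partition, never carried over from optimizer internals.

Moving a node to an unused label (becoming a singleton) scores zero gain
naturally and is allowed, which matters for the refinement pass. In tests
the optimizer is held to the exact global optimum found by exhaustive
enumeration over all set partitions for $N \le 8$, and to agreement with
igraph's Louvain on all-positive networks.

`consensus_partition()` stabilizes repeated stochastic runs via the usual
co-assignment construction: average the co-assignment indicator over runs,
zero entries below the threshold (default 0.5), re-cluster with the same
optimizer, and iterate to a fixed point. When thresholding removes every
positive entry — e.g. two perfectly complementary partitions at threshold
0.75 — no pair has consistent support and the all-singleton partition is
returned.

## Centrality and hubs

Strength and diversity are computed on the cohort-mean FC network (the
per-subject route stays available). With the node-level negative share
$f_i = s^{-}_i / (s^{+}_i + s^{-}_i)$:

* generalized strength $s^{*}_i = s^{+}_i - f_i\,s^{-}_i$ — reduces to the
  plain strength on all-positive networks and to $-s^{-}_i$ for a purely
  negative node;
* diversity per layer: the entropy of the node's strength distribution
  across the $m$ modules, $h_i = -\frac{1}{\log m}\sum_u p_i(u)\log
  p_i(u)$ with $p_i(u) = s_i(u)/s_i$ and $0\log 0 = 0$; normalization by
  $\log m$ puts $h \in [0,1]$ regardless of logarithm base (natural logs
  used). $m = 1$ or a zero-strength layer yields $h = 0$;
* generalized diversity $h^{*}_i = h^{+}_i - f_i\,h^{-}_i$.

The negative-share factor is node-level by default because the rescaling
is meant to discount *that node's* negative connections; a global factor
$v^{-}/(v^{+}+v^{-})$ is available via `scale = "global"`.

A node is a **hub** when both $s^{*}$ and $h^{*}$ are *strictly* above
their across-node means — strict, so a fully degenerate profile (all nodes
identical) has no hubs.

## Reproducibility statistics

Similarity between two partitions is measured on their contingency table
with natural logarithms:

* normalized mutual information $\mathrm{MI} = 2I(P;Q)/(H(P)+H(Q))$, with
  $0/0 := 0$ so a trivial one-module partition scores 0 against anything
  non-trivial;
* variation of information $\mathrm{VoI} = H(P)+H(Q)-2I(P;Q)$, a metric on
  partitions, normalized by $\log N$ so the singleton-vs-one-module pair
  scores exactly 1.

These normalizations are standard but not unique; both are switchable
(`normalize = "none"`) and the raw-nat VoI keeps the metric axioms tested
in the suite.

The chance baseline is a **weight-permutation null network**: the 630
upper-triangular weights are permuted uniformly (seeded) and mirrored back.
This preserves the weight multiset — hence $v^{+}$ and $v^{-}$ exactly —
and the complete-graph topology, while destroying where the weights sit,
i.e. the community structure. On the planted cohort the null's best
partition has mean MI $< 0.3$ with the planted truth.

Two report levels mirror the two study questions:

* `subject_level_report()` — partition each subject's own network, compute
  MI/VoI over all unordered subject pairs; repeat on one null network per
  subject.
* `group_randomization_report()` — repeatedly split the cohort into
  groups (seeded shuffle; sizes differ by at most one when the division is
  uneven), average FC within groups, partition the group means, and pool
  pairwise MI/VoI over group pairs and randomizations, with a parallel
  null branch. The default is 1000 randomizations; the acceptance-scale
  runs in this package use 50, which is ample for the directional
  contrasts examined.

Within one report, all *observed* partitions share a single derived
optimizer seed. This is deliberate: if two subjects (or two groups) have
identical inputs, they must get identical partitions, so the dispersion in
the report reflects differences between datasets rather than optimizer
randomness. Null branches are seeded per item, since each null is its own
random draw.

## The synthetic cohort

The generator plants a known modular structure so that recovery is a
testable claim. The default design emulates the reference study scale: 40
subjects, 165 timepoints, 36 regions, six modules of sizes
5/4/8/8/3/8. The generating correlation matrix has unit diagonal, 0.6
within modules, 0.05 between modules, and −0.2 between two designated
module pairs (the first two modules against the last), reflecting that
anti-correlations exist but are the minority; with these defaults the
exact partial-correlation matrix of the generating model has 538 positive
versus 92 negative off-diagonal entries, and the estimated cohort-mean FC
matrix inherits the positive majority.

Per subject, independent Gaussian jitter (sd 0.05) is added to every
off-diagonal entry, and each subject's matrix is repaired to positive
definiteness before sampling $T$ i.i.d. multivariate-normal vectors
(Cholesky factorization). Sampling is i.i.d. in time because every
downstream statistic uses zero-lag correlation only; temporal
autocorrelation would change effective degrees of freedom but not the
targets of the analysis.

**Positive-definiteness repair.** Eigenvalues are floored and the matrix
rescaled to unit diagonal. For the *planted* matrix the floor is a small
epsilon and the repair must not move any entry by more than 0.05 —
otherwise the requested correlation configuration is declared infeasible.
(The default configuration is already positive definite, minimum
eigenvalue 0.4, so no repair occurs.) For *jittered subject* matrices the
floor is the planted matrix's smallest eigenvalue: symmetric jitter of sd
$\sigma$ over $N$ nodes spreads eigenvalues by roughly $2\sigma\sqrt{N}
\approx 0.6$, so a tiny floor would leave subject covariances
near-singular and their true partial correlations dominated by inversion
noise. Flooring at the planted minimum keeps subject conditioning equal to
the planted matrix's while leaving the block structure (which lives in the
top eigenvalues) untouched.

**What the generator does not emulate:** hemodynamic response,
scanner/physiological noise, motion, temporal autocorrelation, or
empirically calibrated effect sizes. Passing tests on this cohort shows
the pipeline recovers structure it is told is there and separates it from
chance; it does not certify performance on real acquisitions.

**A ceiling worth knowing.** The between-group FC reproducibility
correlation is bounded by the signal-to-noise of partial-correlation
estimation itself. The planted z-scale signal has variance
$\sigma^2_{\text{sig}} \approx 0.0036$ across the 630 connections, while a
10-subject group mean carries sampling noise of roughly
$\tfrac{1}{10}(T-N)^{-1}$, giving a ceiling of about 0.83 for pairwise
group r *with zero between-subject variability*; the default jitter takes
a further share, placing observed values around 0.75–0.80. The suite
therefore asserts all pairwise group r > 0.7 — high, and near the ceiling
the design permits — rather than a bound the stated design cannot reach.

## Problem sizes used by the test and acceptance runs

All sizes are the package's own choices for a desk-scale, fully
reproducible run: the default cohort (40 × 165 × 36) with 100 optimizer
restarts for the cohort-mean partition; 50 grouping randomizations with
10 restarts per group partition in the acceptance script (5 restarts in
the seed-sweep tests, which repeat everything across 5 master seeds);
exhaustive-enumeration cross-checks at $N \le 8$; and an 8-subject,
12-node configuration for the byte-identical determinism check of the full
pipeline bundle.

## Known limitations

* Plain inversion assumes $T > N$ comfortably; for heavily parcellated
  data enable shrinkage (the intensity estimate is deliberately simple).
* $Q^{*}$ maximization is NP-hard; the optimizer is exact only where
  exhaustively verified ($N \le 8$) and otherwise a well-tested heuristic.
* MI/VoI normalizations are a convention; compare across studies only
  after matching them.
* The permutation null preserves the weight distribution but not the
  strength sequence; a strength-preserving null would be stricter and is
  not implemented here.
* NIfTI inputs are assumed co-registered to the atlas grid; no spatial
  preprocessing of any kind is performed.
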