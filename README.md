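# signedfc

Signed weighted functional-connectivity network analysis for
resting-state ROI time series: partial-correlation network construction,
modularity partitioning for networks with positive *and* negative
weights, hub detection via generalized strength and diversity, and
reproducibility statistics for modular organization.

## The problem

Resting-state fMRI studies summarize brain organization as a network:
regions of interest (ROIs) are nodes, and statistical dependence between
their time courses is the edge weight. Using *partial* correlation —
the correlation between two regions after regressing out all others —
gives "direct" functional connectivity, and it is naturally signed:
regions can be correlated or anti-correlated. Most graph statistics
assume nonnegative weights, so every quantity here is a signed
generalization in which negative connections matter but are auxiliary to
positive ones.

For a cohort, the questions are: how does the mean network partition
into modules, which regions are hubs, and how reproducible is that
modular organization across subjects and across random subject groups?

## The statistics

With sign layers $w^{\pm}$, node strengths $s^{\pm}_i$, and layer totals
$v^{\pm}$:

* **Modularity.** Each layer is scored by standard weighted modularity
  $Q^{\pm} = \frac{1}{v^{\pm}}\sum_{ij}(w^{\pm}_{ij} -
  s^{\pm}_i s^{\pm}_j / v^{\pm})\,\delta(M_i,M_j)$, combined as
  $Q^{*} = Q^{+} - \frac{v^{-}}{v^{+}+v^{-}}Q^{-}$ and maximized by a
  seeded Louvain-type optimizer (`maximize_modularity()`), exhaustively
  verified against full set-partition enumeration for small networks.
* **Centrality.** Generalized strength
  $s^{*}_i = s^{+}_i - \frac{s^{-}_i}{s^{+}_i+s^{-}_i}s^{-}_i$ and
  generalized diversity $h^{*}_i$ (normalized entropy of a node's
  strength across modules, per sign layer, combined the same way). A
  **hub** is strictly above the mean in both.
* **Reproducibility.** Normalized mutual information
  ($2I/(H_P+H_Q)$) and variation of information
  ($(H_P+H_Q-2I)/\log N$) between module partitions, compared against
  weight-permutation null networks that preserve the weight multiset
  exactly while destroying community structure.

A planted-partition cohort simulator (multi-subject block-structured
Gaussian time series with per-subject variability) makes the whole
pipeline testable end to end without any imaging data.

## Worked example

```r
library(signedfc)

spec   <- planted_partition_spec()        # 40 subjects x 165 timepoints x 36 ROIs
cohort <- generate_cohort(spec)           # six planted modules, signed blocks
fcs    <- lapply(cohort, subject_fc)      # Fisher-z partial correlation per subject
avg    <- mean_fc(fcs)                    # cohort mean (+ SD companion)
net    <- signed_network(avg$mean)
net
#> signed_network: 36 nodes, 630 edges (v+ = 37.868, v- = 6.636)

mod <- maximize_modularity(net, n_restarts = 100, seed = 1)
mod
#> modularity_result: 6 modules, Q* = 0.6469 (Q+ = 0.6194, Q- = -0.1848)
partition_mi(mod$partition, true_partition(spec))
#> [1] 1
```

The optimizer recovers the six planted modules exactly (normalized MI of
1 with the ground truth), with a high Q\*: most positive weight sits
within modules. Centrality and hubs on the same network:

```r
prof <- centrality_profile(net, mod$partition)
head(prof[, c("roi", "s_star", "h_star", "is_hub")], 5)
#>    roi   s_star    h_star is_hub
#>  ROI23 1.127295 0.3565659   TRUE
#>  ROI12 1.126077 0.3339769   TRUE
#>  ROI11 1.124653 0.3452369   TRUE
#>  ROI14 1.114932 0.3213257   TRUE
#>  ROI20 1.110452 0.4120938   TRUE
```

Subject-level reproducibility versus chance:

```r
subject_level_report(fcs, n_restarts = 10, seed = 2)
#> reproducibility_report (subject level, 780 pairs):
#>   MI  0.996 +/- 0.012  (null 0.130 +/- 0.056)
#>   VoI 0.004 +/- 0.011  (null 0.689 +/- 0.046)
```

Observed partitions agree almost perfectly across subjects (MI near 1,
VoI near 0), while null networks sit at chance (MI ≈ 0.13) — the planted
modular organization is far stronger than typical in-vivo data, which is
exactly what makes it a useful correctness benchmark.

`run_pipeline(pipeline_config(), "out/")` runs everything above plus the
group-level analyses and writes a complete TSV/JSON bundle with a
manifest; `inst/scripts/signedfc` exposes the same steps as shell
subcommands (`simulate`, `connect`, `modules`, `hubs`, `reproduce-fc`,
`reproduce`, `run`).

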