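# gigiva

Multi-subject fMRI decomposition with **GIG-ICA** (group information guided
independent component analysis) and **IVA-GL** (independent vector analysis,
Gaussian SCV model refined by a Laplace SCV model), plus the simulation and
evaluation machinery needed to compare them.

Spatial ICA views an fMRI run as `data (T x V) ~ time courses (T x C) x
spatial maps (C x V)` with maximally independent maps; some maps are brain
functional networks. With M subjects the two estimation strategies differ:

* **GIG-ICA** runs temporal-concatenation group ICA (subject PCA to G1,
  group PCA to G2, Infomax), then estimates each subject-specific component
  by maximizing `F(w) = lambda J(w'X) + (1 - lambda) corr(w'X, r)` on the
  unit sphere of the subject's whitened space, where `J` is log-cosh
  negentropy and `r` the group-level reference map — independence plus
  correspondence, in a deflation manner.
* **IVA-GL** jointly decomposes all subjects, minimizing
  `sum_l 0.5 log det Sigma_l - sum_m log |det W_m|` (IVA-G; `Sigma_l` is the
  cross-subject covariance of source component vector l) and refining with
  the multivariate Laplace score `y_m / ||y_SCV||` (IVA-L). Components are
  aligned across subjects by SCV index.

The package also provides: a multi-subject simulator (Gaussian-blob sources
with per-subject translation/rotation/spread perturbations, optionally
subject-unique sources, HRF-smoothed time courses, Rician noise at a given
CNR), greedy component-template matching and absolute-correlation accuracy
with paired t-tests, one-way ANOVA ICC test-retest reliability with
BH-FDR-masked one-sample t maps, and FNC analysis (signed-network
leading-eigenvector modularity and Q, adjusted mutual information, weighted
graph metrics at sparsity 0.5).

## Worked example

Generate the standard 10-subject simulation (8 common blob sources on a
148 x 148 grid, 150 time points, CNR = 2), run both methods at model order
8, and compare per-subject mean accuracy:

```r
library(gigiva)
run <- run_sim_setting("exp1_quality", seed = 11, cnr = 2)
run$score$tests
#>     domain component          t            p df   comparison
#> 1  spatial        NA -14.210113 1.803004e-07  9 iva - gigica
#> 2 temporal        NA  -9.792896 4.257962e-06  9 iva - gigica
sapply(run$score$tables, function(tb) mean(tb$subject_mean_spatial))
#>       iva    gigica
#> 0.9803687 0.9850233
```

Both methods recover the subject-common sources well at this CNR, and
GIG-ICA is significantly more accurate (negative t: IVA minus GIG-ICA),
spatially and temporally — the per-subject refinement guided by clean group
references beats the joint decomposition when sources are shared.

With a subject-unique source per subject (`exp3_unique`), the direction
reverses for that source: IVA-GL estimates each subject's unique component
directly, while GIG-ICA's group-level reference for it is an across-subject
blur:

```r
run3 <- run_sim_setting("exp3_unique", seed = 21, n_components = 8,
                        by = "component")
subset(run3$score$tests, domain == "spatial" & component == 8)
#>    domain component        t            p df   comparison
#> 8 spatial         8 4.990717 0.0007483948  9 iva - gigica
```

Sweeps (`run_simulation_experiment()`) cover the CNR range 0.5-2, time
points 40-120, varied source counts, and deliberately wrong model orders,
writing per-subject accuracy and Bonferroni-corrected t-test tables to CSV.
`run_realdata_study()` applies the same machinery to preprocessed 4D NIfTI
test-retest data: cross-method matching at |r| > 0.5, a user-supplied list
of meaningful networks, short/long-term map and connectivity reliability
(one-way ICC), modularity reliability (AMI), and weighted graph metrics.

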