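# dkclust

Diffusion-kurtosis fitting and diffusion-compartment clustering for
multi-b-value diffusion-weighted MRI (DWI) of the endometrium.

Endometrial cancer tissue is heterogeneous — necrosis, hypercellular tumor
and infiltrated margins coexist inside one region of interest — and a
single apparent diffusion coefficient per ROI throws that heterogeneity
away. `dkclust` implements an ROI analysis that keeps it, for researchers
working on quantitative DWI of gynecological tissue:

1. **Kurtosis fitting.** The signal decay over b-values
   (500…2500 s/mm²) is modelled as
   `S(b) = S0 · exp(−b·D + b²·D²·K/6)` and fitted per ROI and per voxel
   under box constraints (K ∈ [−0.7, 3.7], D ∈ [0.01, 3]·10⁻³ mm²/s) by
   bound-constrained nonlinear least squares.
2. **Compartment clustering.** Voxel decays, normalized by the fitted
   Se(0) and log-transformed, are clustered by seeded k-means (silhouette
   guides k; the pipeline fixes k = 2). Clusters are refitted on the
   original signals and ordered by mean-K/mean-D: Cluster 2, the high-K/D
   compartment, reads as the complex/hypercellular one.
3. **Cluster-statistic features and classification.** Per-cluster means
   and SDs of D and K form 2/5/12-feature model variants, classified
   tumor-vs-healthy by cross-validated Lasso logistic regression with
   fold-wise Mann–Whitney + Bonferroni selection, correlation pruning,
   AUC with 1000-bootstrap CI and Youden-index metrics.
4. **Group statistics.** Kruskal–Wallis with Dunn–Šidák post-hoc tests,
   Cohen's d and Benjamini–Hochberg adjustment for healthy / tumor /
   peritumor comparisons.
5. **Synthetic phantom.** A seeded generator producing DWI cohorts with
   tissue-dependent (D, K) compartment mixtures, Rician noise added per
   gradient direction before averaging, and full per-voxel ground truth —
   the test bed for every quantitative claim the package makes.

Everything user-facing takes and returns tibbles (with light S3 wrappers
for volumes, fits and reports), composes with the pipe, and has
`tidy()` / `glance()` / `autoplot()` methods.

## Worked example

Simulate one cancer subject, fit, cluster, and inspect the compartments:

```r
library(dkclust)

cfg  <- phantom_config(grid_shape = c(48, 48, 3))
subj <- generate_subject(cfg, group = "EC", seed = 42)

roi   <- extract_roi_signals(subj$dwi, subj$mask, "T")
map   <- fit_voxelwise(roi)
norm  <- normalize_decays(roi, map)
asg   <- cluster_decays(norm, k = 2, seed = 1)
refit <- label_and_refit(roi, asg)

compute_features("two_cluster", refit = refit,
                 subject = "sub01", roi_label = "T")
#> # A tibble: 12 × 5
#>    subject roi   variant     feature      value
#>    <chr>   <chr> <chr>       <chr>        <dbl>
#>  1 sub01   T     two_cluster D1        1.00e- 3
#>  2 sub01   T     two_cluster K1        8.89e- 1
#>  3 sub01   T     two_cluster stdD1     9.71e- 5
#>  4 sub01   T     two_cluster stdK1     1.30e- 1
#>  5 sub01   T     two_cluster KDratio1  8.88e+ 2
#>  6 sub01   T     two_cluster D2        4.97e- 4
#>  7 sub01   T     two_cluster K2        1.79e+ 0
#>  8 sub01   T     two_cluster stdD2     7.77e- 5
#>  9 sub01   T     two_cluster stdK2     2.18e- 1
#> 10 sub01   T     two_cluster KDratio2  3.60e+ 3
#> 11 sub01   T     two_cluster Dratio    2.01e+ 0
#> 12 sub01   T     two_cluster Kratio    4.97e- 1
```

The tumor ROI was generated as a 50/50 mixture of a
(D = 1.0·10⁻³ mm²/s, K = 0.9) and a (D = 0.5·10⁻³, K = 1.8) compartment:
the ordered clusters recover both — Cluster 1 is the low-K/D compartment
(K1 ≈ 0.89, D1 ≈ 1.0·10⁻³), Cluster 2 the high-K/D one (K2 ≈ 1.79,
D2 ≈ 0.50·10⁻³) — and `KDratio2 ≈ 3600` s/mm² marks it as the
complex/hypercellular compartment. `stdK2` is the dispersion feature that
separates pathological from healthy tissue downstream.

The full pipeline over a cohort, ending in classification reports and
group statistics:

```r
run <- run_pipeline(make_demo_config("small", seed = 1))
glance(run$reports[["T_vs_H.cluster2"]])
run$stats |> dplyr::filter(comparison == "H vs T")
autoplot(run$reports[["T_vs_H.cluster2"]])             # pooled ROC
plot_dispersion_scatter(run$features)                  # stdK vs stdD per ROI
```

On the default synthetic cohort the T-vs-H classification is fully
separable (median fold AUC = 1.0) and the Dunn–Šidák contrasts flag
K(T) > K(H) and D(T) < D(H) at α = 0.05 — the orderings the tissue model
is built to produce.

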