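---
title: "Kurtosis fitting and diffusion-compartment clustering for endometrial DWI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kurtosis fitting and diffusion-compartment clustering for endometrial DWI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkclust)
library(dplyr)
```

## The problem

Endometrial cancer tissue is heterogeneous: necrotic cores, densely packed
neoplastic cells and infiltrated margins coexist within a single lesion.
Conventional diffusion MRI summarizes a region of interest (ROI) with one
apparent diffusion coefficient, discarding precisely that heterogeneity.
`dkclust` implements an analysis that keeps it: multi-b-value
diffusion-weighted signals are fitted with the kurtosis representation, the
per-voxel decay curves are clustered into diffusion compartments, and
cluster-level statistics become features for classifying tumor (T) and
peritumor (PT) tissue against healthy endometrium (H).

Because no public endometrial DWI dataset with this acquisition exists, the
package ships a first-class synthetic phantom generator that reproduces the
statistical structure the analysis assumes, with per-voxel ground truth for
recovery testing. All results the package reports are computed on such
synthetic cohorts; none of the patient-level numbers of any in-vivo study
are claimed.

## Signal model

The kurtosis representation models the direction-averaged signal at
diffusion weighting $b$ (s/mm²) as

$$S(b) = S_0 \, \exp\!\left(-b D + \tfrac{1}{6} b^2 D^2 K\right),$$

where $D$ (mm²/s) is the apparent diffusivity corrected for non-Gaussian
bias and $K$ (dimensionless) the apparent kurtosis — the deviation of the
water-displacement distribution from Gaussian, a proxy for microstructural
complexity. The representation is a truncated cumulant expansion: it is
descriptive, not microstructurally specific, and it degrades at large
$b\,D\,K$. The default b-value scheme is (500, 800, 1000, 1500, 2000,
2500) s/mm², acquired along three gradient directions that are averaged.

Fitting is bound-constrained nonlinear least squares with
$K \in [-0.7, 3.7]$ and $D \in [0.01, 3]\times 10^{-3}$ mm²/s:

```{r fit}
b <- bvalue_scheme()
y <- kurtosis_signal(s0 = 1000, d = 1e-3, k = 0.8, b = as.numeric(b))
tidy(fit_kurtosis(y, b))
```

### Numerical choices

* **Initialization.** $\ln S(b)$ is linear in $(\ln S_0,\, D,\, D^2K/6)$, so
  a closed-form linear solve supplies the primary start; noiseless decays
  are inverted essentially exactly from it. A two-point log-slope start and
  five fixed interior points serve as deterministic fallbacks, so fitting
  involves no random numbers.
* **Optimizer.** Bounded quasi-Newton (PORT/`nlminb`) on the sum of squared
  residuals with an analytic gradient; function and step tolerances
  $10^{-10}$. Looser tolerances visibly bias noisy fits; tighter step
  tolerances produce spurious "false convergence" flags.
* **`fit_ok` semantics.** A voxel-wise fit is usable only if the optimizer
  converged *and* the estimate is strictly interior to the D/K box. A
  boundary-pinned estimate is censored rather than identified — typically a
  noise-dominated voxel whose decay looks concave — and including such
  values would bias cluster means and SDs. Voxels with any nonpositive
  intensity are excluded up front (the log-normalization below needs
  positivity) rather than clipped.
* **Degenerate inputs.** A constant (non-decaying) row pins $D$ at its
  lower bound or fails convergence; either way it is flagged, never fatal.

## Clustering into diffusion compartments

Within an ROI, each retained voxel's decay is normalized by its own fitted
$S_e(0)$ and log-transformed, $\ln(S(b)/S_e(0))$, removing proton-density
and coil-gain differences so that clustering sees decay *shape* only.
k-means (k-means++ seeding, 10 restarts, Lloyd iterations, Euclidean
distance on the 6-vector) partitions the voxels; the mean silhouette over
candidate $k \in \{2, 3, 4\}$ guides the choice of $k$, and the pipeline
default fixes $k = 2$ — the typical silhouette choice in endometrial
tissue, kept fixed for comparability across subjects. No additional scaling
of the b-axes is applied: the log transform is the only preprocessing.

Clusters are then **refitted on the original signals** voxel by voxel, and
ordered by their mean-$K$/mean-$D$ ratio: Cluster 1 has the minimum ratio,
Cluster 2 the maximum (ties break toward the lower original index, for
determinism). High $K/D$ reads as high complexity and hypercellularity.
Clusters with fewer than 5 usable voxels are flagged unusable and their
features emitted as missing, rather than producing unstable statistics from
a handful of voxels.

An open representational question: cluster means and SDs here are computed
from the voxel-wise fits within each cluster (fit-then-aggregate). The
alternative — fitting the cluster-mean signal — yields systematically
higher $K$, because mixing distinct decays adds apparent kurtosis; the
package exposes that effect through `fit_roi_average()` but uses
fit-then-aggregate for all cluster features.

## Feature sets and classification

Four model variants produce subject-level feature vectors per ROI:

| variant | features |
|---|---|
| `conventional` | $D$, $K$ from the ROI-averaged fit (2) |
| `one_cluster` | $D$, $K$, std$D$, std$K$, $K/D$ over the whole ROI (5) |
| `cluster1` / `cluster2` | the same 5 statistics over one ordered cluster |
| `two_cluster` | both clusters' 5 statistics + $D_1/D_2$ + $K_1/K_2$ (12) |

(Feature counts for two-cluster models of this kind are sometimes quoted
as fifteen when cluster statistics are tallied differently; this package
defines and always emits exactly twelve, and the identities
$KDratio_i = K_i/D_i$, $Dratio = D_1/D_2$, $Kratio = K_1/K_2$ are asserted
on every emitted row.)

Classification of T-vs-H or PT-vs-H is stratified 5-fold cross-validation;
within each training split, and only there: a two-sided Mann–Whitney test
per feature with Bonferroni threshold $p \le \alpha/n$ ($n$ = the variant's
feature count), ascending-p ordering, greedy pruning of features with
$|\rho| \ge 0.8$ Pearson correlation against an already-kept feature,
z-score standardization, then L1-penalized logistic regression. If no
feature survives Bonferroni, the single lowest-p feature is kept with a
warning — a fold must emit a predictor. The Lasso penalty is parameterized
as an inverse regularization strength $C$ (default 1, fixed — deterministic
by default), mapped internally to a `glmnet` lambda of $1/(nC)$.

Held-out scores give per-fold AUC and Youden-index metrics (threshold over
midpoints of adjacent distinct scores, ties toward the lower threshold;
all-equal scores fall back to the all-positive assignment). Reported
summaries are fold medians with 5–95% fold percentiles, plus a
1000-replicate bootstrap percentile interval on the pooled out-of-fold AUC
(single-class resamples are redrawn).

## Group statistics

`group_stats()` compares subject-mean $D$ and $K$ across H/T/PT with a
tie-corrected Kruskal–Wallis test, Dunn's rank-based pairwise z-tests under
a Šidák correction ($1-(1-p)^m$, with the per-comparison level
$1-(1-\alpha)^{1/m}$ also reported), and Cohen's d per pair.
Benjamini–Hochberg adjustment is exposed separately (`bh_adjust()`) for
p-value families assembled by the caller; which rows form a family is a
reporting decision the package does not impose. The Mann–Whitney kernel is
exact for tie-free samples with $n_1 n_2 \le 400$ and otherwise uses the
tie-corrected normal approximation without continuity correction, which
makes the two-group Kruskal–Wallis identity $H = z^2$ hold exactly.

## The synthetic phantom

`generate_subject()` builds a voxel grid (default 64×64×5) with ellipsoidal
endometrial ROIs (~150–400 voxels), a 2-voxel in-plane peritumoral ring
around T, and a disjoint bladder disk. Per voxel, a diffusion compartment
is sampled by its mixing fraction and $(S_0, D, K)$ drawn from truncated
Gaussians confined to the fit box (rejection sampling), so recovery tests
are not boundary-pinned by construction. The noise-free decay is evaluated
on the scheme, independent Rician noise $\sqrt{(A+n_1)^2+n_2^2}$ is added
per direction, and the three directions are averaged — noise enters before
averaging, as in acquisition.

Default tissue parameters are order-constrained inventions, not measured
values (no quantitative endometrial $(D,K)$ reference exists at this
acquisition): healthy endometrium is a single compartment
($D=1.4\times10^{-3}$, $K=0.6$); tumor has two compartments
($1.0\times10^{-3}, 0.9$) and ($0.5\times10^{-3}, 1.8$) at equal fractions —
lower $D$ and higher $K$ than healthy tissue; peritumor has the largest
kurtosis dispersion ($\mathrm{sd}(K)=0.45$ per compartment); the bladder is
free-water-like ($D=2.9\times10^{-3}$, just inside the fit box) so its
signal at $b=2500$ s/mm² is pure noise floor — which is what
`estimate_snr()` exploits, dividing the median ROI signal over all b-values
by the bladder SD at maximal b. The default noise scale
$\sigma = 15$ against $S_0 \approx 1000$ puts the healthy-tissue SNR at the
highest b-value near 7, the minimum observed in vivo at this protocol.

What the phantom deliberately does **not** emulate: anatomical geometry,
partial-volume mixing within a voxel, diffusion anisotropy (directions are
i.i.d. noise replicates), EPI distortion, or spatially correlated noise.
Passing recovery and ordering tests on this phantom therefore demonstrates
that the estimator and feature machinery are correct and well-calibrated
under the model's own assumptions — not that the pipeline's in-vivo
accuracy is established.

## Problem sizes and reproducibility

The bundled demo configurations are `make_demo_config("small")` — 8 healthy
+ 8 cancer subjects on a 48×48×3 grid, the size used throughout the test
suite and the acceptance script — and `"full"`, 20 + 18 on the default
grid, mirroring a realistic cohort. Recovery experiments use 300 voxels per
condition; cluster-recovery and ordering properties use 20 seeded
replicates. Every stochastic stage (subject sampling, k-means, fold
assignment, bootstrap) derives its seed deterministically from the master
seed, so `run_pipeline()` is bit-reproducible: the run manifest records md5
hashes of the canonical text renderings of every major output, and repeated
runs with one seed produce identical hashes.

## Known limitations

* The kurtosis representation is used outside its strict convergence radius
  at the highest b-values for large $D\,K$; fits remain well-defined
  (bounded least squares) but parameter interpretation weakens there.
* Magnitude (Rician) noise biases $K$ at low SNR even on averaged data; the
  voxel-mean error stays within ~5% at SNR ≳ 20 but grows quickly below.
  The pipeline accepts externally denoised volumes; it does not denoise.
* One-compartment-per-voxel sampling makes cluster recovery easier than
  partial-volume reality; agreement rates on the phantom are upper bounds.
* Small cohorts make fold-level metrics coarse (a 2-subject test fold
  quantizes AUC in steps of 0.5); the pooled out-of-fold AUC is the more
  stable summary and is the one bootstrapped.
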