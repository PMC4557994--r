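---
title: "Comparing structural and functional brain connectivity between groups"
author: "conncompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing structural and functional brain connectivity between groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conncompare)
```

## The problem

Given two groups of subjects, each with region-pair connectivity networks
of several kinds — structural networks from diffusion MRI and functional
networks from fMRI — we want to know *where* and *how strongly* the groups
differ: globally, within lobe-pair groupings of connections, and at
individual connections. `conncompare` implements the full chain from
network construction to multi-level visualization, with a synthetic
cohort generator so that every stage can be validated against known
ground truth.

## Network construction

**Functional.** Each subject contributes a T × r matrix of regional mean
time series. `pearsonNetwork()` gives fMT, the full Pearson correlation of
every pair. `partialCorrelationNetwork()` gives fPC: with p the inverse of
the sample covariance matrix (unbiased T−1 denominator), the partial
correlation is r_ij = −p_ij / √(p_ii p_jj) — the dependence of regions i
and j with all other regions' influence removed. The standard square-root
form is used throughout; the inverse requires T − 1 ≥ r and reasonably
conditioned data, and an optional diagonal-loading `shrinkage` (covariance
+ λI, default λ = 0) is available for marginal cases. Columns with zero
variance cannot be correlated and have their edges masked with a warning.
Both networks are invariant to per-column affine rescaling of the series.

**Structural.** `minCostPathNetwork()` runs a shortest-path search through
a voxel cost field. All voxels of the source region are seeded at cost 0
(travel inside the source region is free — which is why adjacent regions
get near-zero cost), a step u→v costs (step length in mm) × (cost(u) +
cost(v))/2, and the edge weight DMC(i, j) is the minimum over target-region
voxels of the cumulative path cost. DFA(i, j) is the sum of FA over the
optimal path's voxels divided by the straight-line distance between its
endpoints. Design choices worth knowing:

* **Local cost is pluggable.** The default `defaultCostFromFA()` is
  c(v) = 1 − FA(v) clipped to [10⁻³, 1]: traversal is cheap along
  coherent, high-FA white matter. Any non-negative cost image can be
  supplied to `VoxelGrid()` instead.
* **Neighborhood**: 26-connectivity by default (less metrication error
  than 6-connectivity); step lengths are physical center-to-center
  distances, so anisotropic voxels are handled.
* **DFA denominator**: endpoint straight-line distance by default; the
  path arc length is available via `distance = "arc"`. FA is summed over
  path voxels, endpoints inclusive.
* **Determinism**: among equally cheap target voxels the smallest linear
  voxel index wins, so repeated runs produce identical paths.
* Costs are undirected, so the matrices are symmetric by construction and
  every pair on a connected grid receives a finite weight — the graph is
  always fully connected. Regions with no voxels (which happens after
  aggressive resampling of real atlases) have their edges masked rather
  than failing the run. For externally computed *directed* costs,
  `symmetrizeDirected()` takes the minimum of the two directions and the
  companion DFA value of whichever direction won (ties resolve to the
  i→j direction, i < j).

## Per-edge statistics and the M_eff correction

`edgeRegression()` fits, per edge, OLS of weight on intercept + group +
covariates over the subjects observed for that edge. Group is coded 0/1
with group 1 the group of interest, so positive t means group 1 > group 0.
p-values are two-sided with df = n_used − (number of design columns).
Edges whose post-deletion design is rank deficient are masked with a
warning; zero residual variance masks t and p but keeps the coefficient.
With no covariates the group t is algebraically the pooled two-sample t,
which the test suite verifies to 10⁻¹⁰.

Missing values follow one of two policies (`handleMissing()`): `exclude`
(per-edge listwise deletion; the default) or `impute_group_mean` (replace
a missing entry by that edge's group mean; an edge missing for a whole
group stays masked). Both appear in practice depending on whether a
regional dropout should shrink n or be smoothed over.

Because edges of a brain network are mutually dependent, Bonferroni over
all M_G = r(r−1)/2 tests is too strict. `effectiveNumberOfTests()`
computes the Pearson correlation matrix *between edges* across the pooled
subjects of both groups and applies the Li & Ji eigenvalue rule
f(λ) = 1[λ≥1] + (λ−⌊λ⌋), summed over all eigenvalues. Two numerical
points:

* When M_G > n the M_G × M_G correlation matrix is rank deficient and
  must not be materialized: the non-zero eigenvalues are obtained from
  the n × n Gram matrix of the standardized edge rows. This is exact —
  the remaining eigenvalues are zero and f(0) = 0.
* The estimator is capped below by 1 (two perfectly duplicated edges give
  M_eff = 1) and above by M_G; with n subjects it can reach at most about
  2(n−1) because each of the ≤ n−1 non-zero eigenvalues contributes less
  than 2. Pooling both groups without residualizing covariates is the
  simplest defensible choice for "the" dependence structure of a network
  kind; the correction is computed per network kind with no extra
  correction across kinds (the kinds are themselves strongly dependent).

`correctionSpec()` records α (default 0.05), M_G, M_eff, the adjusted
threshold α_adj = α/M_eff and the worm-plot scale
s = log10(α)/log10(α_adj).

`clusterShiftTests()` runs, per lobe-pair cluster, a one-sample two-sided
t-test of the member edges' t statistics against zero. It detects
coordinated sub-threshold shifts that individual-edge thresholds miss.
Clusters with fewer than two usable edges or zero variance are masked
with a warning rather than guessed at.

`welchFromSummary()` and `chisq2x2()` cover the demographic table:
group comparisons of age, education and similar variables are routinely
published only as mean ± SD and n, and Welch's statistic with
Welch–Satterthwaite df is fully determined by those summaries.

## Visualizations as data

Each figure is computed as a deterministic plot-data structure with a thin
ggplot wrapper, so every visual encoding is testable without image
comparison.

* **Worm plots** (`wormPlotData()`): edges grouped by lobe pair, sorted
  ascending by t within each cluster (ties broken by edge index), plotted
  at y = −log10(p)·sign(t)·s. The construction of s guarantees that an
  edge at p = α_adj sits exactly at |y| = −log10(α), so a single
  reference line serves all network kinds — the suite checks this
  identity to 10⁻¹² over randomized corrections. p-values that underflow
  to zero are clipped to the smallest positive double with a warning.
* **Connectograms** (`connectogramData()`): regions on a circle in
  contiguous cluster blocks at 360°/r spacing; edges with p < α_adj drawn
  as chords, red for t > 0 and blue for t < 0, opacity affine in
  −log10(p) from the threshold to the strongest drawn edge over
  [0.3, 1]; node saturation affine in significant-edge degree over
  [0.25, 1]. Zero significant edges is a valid, empty connectogram.
* **Bi-modal comparison plots** (`bimodalPlotData()`): per network kind a
  1D histogram of group-mean edge weights per group on shared bins, and
  per structural × functional pair a 2D histogram whose bins mix blue
  (pure group 1), red (pure group 0) and magenta (both) in proportion to
  the group mix, with opacity proportional to max-normalized bin count;
  `t_stats` mode plots single green histograms of the edge t statistics.
  Defaults are 100 bins (1D) and 64 × 64 (2D); the encodings, not the
  constants, are the contract. Histogram counts are conserved — per-group
  bins sum to the number of finite edges.
* **Matrix views** (`matrixPlotData()`): the symmetric r × r weight or t
  matrix with a null diagonal, for runs with too many significant edges
  for a readable connectogram.

## The synthetic cohort generator

`simulationConfig()` fixes the study conditions; the defaults — 5 lobe
clusters × 6 regions (r = 30, M_G = 435), 30 + 30 subjects, T = 200
timepoints, within/between-cluster correlations 0.3/0.05, noise SD 0.1,
a standard-normal `age` and Bernoulli(0.5) `sex` covariate — are a
desk-scale cohort a connectivity study of this size would recognize,
small enough that the whole suite runs in minutes.

* `simulateTimeseriesCohort()` draws each subject's T × r series from a
  zero-mean multivariate normal with block-structured correlation. Group
  effects are injected on the Fisher-z scale (z shifts keep the target
  matrix valid) as `effectSize`/√(T−3), i.e. `effectSize` is standardized
  against the sampling SD of a subject-level z-transformed correlation.
  Non-positive-definite targets are a configuration error, not a silent
  repair.
* `simulateStructuralScene()` lays the regions out as spatial blocks in a
  small slab, connects designated pairs by high-FA ridges (base FA 0.2,
  ridge FA 0.8, voxel noise SD 0.05), and scales group-1 ridge FA by
  `faGroupScale`; under the default cost 1 − FA, lowering ridge FA in
  group 1 provably raises that pair's DMC.
* `simulateEdgeCohort()` skips images entirely:
  w = μ_e + β_e·group + γ·age + λ·u + ε with β non-zero only on the
  designated edges, an optional shared latent factor u to induce
  between-edge correlation (off by default so null cohorts have
  independent edges), and iid Gaussian noise. This is the workhorse for
  calibration and power experiments.

Everything is a deterministic function of `seed`.

What the generator does *not* emulate: hemodynamics, autocorrelated BOLD
noise, head motion, scanner effects, realistic DWI signal or anatomy. A
passing suite therefore demonstrates that the statistics and search are
correct and calibrated under the stated model — not that any preprocessing
pipeline upstream of the package is adequate for real data.

## Numerical and design notes

* Edge linearization is row-major over the strict upper triangle; any
  fixed bijection works, this one is conventional and is exposed via
  `buildEdgeIndex()` / `edgeToIndex()` / `indexToEdge()`.
* Cluster-pair labels are unordered and canonicalized alphabetically
  (`Fro/Temp`, never `Temp/Fro`); with g clusters all g(g+1)/2 pairs,
  same-lobe pairs included, are treated as separate worms.
* Region adjacency derived from a label image means sharing a voxel face
  (6-connectivity); `filterAdjacentEdges()` masks adjacent-pair edges and
  passes everything else through bit-identically, supporting the check
  that the near-zero DMC histogram peak is explained by adjacent pairs.
* Covariance uses the unbiased T−1 denominator (irrelevant to
  correlations, fixed for the precision-matrix contract).
* The sample sizes used by the heavier checks are 200 null cohorts and
  100 effect replicates at r = 30, n = 30 + 30, and 100 random ≤ 4×4×1
  grids against the exhaustive path oracle; the end-to-end determinism
  run uses a 9-region atlas with 5 + 5 subjects and T = 40.

## Limitations

Image preprocessing (segmentation, registration, motion and eddy
correction, filtering, nuisance regression) is out of scope: inputs are
already-cleaned time series, label/FA images or precomputed networks. The
default 1 − FA cost is a deliberately simple stand-in for more elaborate
anisotropy-derived cost models; conclusions about DMC magnitudes depend
on the chosen cost image. The M_eff estimate is rank-limited by the
subject count, so with M_G ≫ n the correction is necessarily coarser than
the nominal edge count suggests. No network-based statistic, permutation
testing, FDR, or graph-theory metrics are provided.
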