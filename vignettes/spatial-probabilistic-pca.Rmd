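---
title: "Spatially aware probabilistic PCA: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially aware probabilistic PCA: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`sppca` performs dimension reduction on a gene × location expression matrix
$Y$ ($m$ genes, $n$ locations with coordinates $s_1, \dots, s_n$) under the
latent factor model

$$Y = (XB)^\top + WZ + E, \qquad E_{ji} \sim N(0, \sigma_0^2),$$

where $X$ is an $n \times q$ covariate matrix (intercept only by default),
$W$ is an $m \times d$ loading matrix constrained to be orthonormal
($W^\top W = I_d$, the probabilistic-PCA identifiability device), and each
row of the $d \times n$ factor matrix $Z$ carries a Gaussian-process prior
over the tissue,

$$Z_{l\cdot} \sim \mathrm{MVN}(0, \sigma_0^2\,\tau\,K), \qquad
K(s_i, s_j) = \exp(-\lVert s_i - s_j\rVert^2/\gamma).$$

A single $\tau$ is shared by all factors (scale homogeneity); it measures
spatial factor variance relative to residual noise. Expression is assumed
standardized per gene (mean 0, sample SD 1) before fitting.

Estimation integrates out $B$ and $Z$: after projecting the data columns
onto the orthogonal complement of $X$ (per-gene centering for an
intercept-only design), the vectorized projected matrix is
$\mathrm{MVN}(0, \sigma_0^2(\tau K \otimes WW^\top + I))$. All computations
run in the eigenbasis $K = U \Lambda U^\top$: the log-determinant is
$d \sum_k \log(1 + \tau\lambda_k)$ and the quadratic form needs only
$A = W^\top Y U$, giving $O(r(md + n))$ likelihood evaluations for a rank-$r$
kernel. For fixed $\tau$, the optimal $W$ is the top-$d$ eigenvector set of
$Y U\,\mathrm{diag}(\tau\lambda_k/(1+\tau\lambda_k))\,U^\top Y^\top$
(obtained from an SVD of $YU\,\mathrm{diag}(\sqrt{c_k})$, never forming the
$m \times m$ matrix), $\sigma_0^2$ is profiled in closed form as the residual
quadratic divided by $mn$, and $\tau$ is maximized by a 21-point log-spaced
grid on $[10^{-10}, 10^{10}]$ followed by golden-section refinement (via
`stats::optimize`) of the bracketing interval, ties broken toward the weaker
prior. The spatial PCs are the posterior means
$E[Z_{l\cdot} \mid Y] = U\,\mathrm{diag}(c_k)\,U^\top (W^\top Y)_{l\cdot}^\top$.
Both the likelihood and the posterior are validated in the test suite
against dense multivariate-normal oracles on small instances before any
large run.

The degrees-of-freedom convention divides the profiled $\sigma_0^2$ by $mn$
rather than $m(n-q)$; with $q = 1$ and the sample sizes this package targets
the difference is negligible, and the simpler convention keeps the profile
likelihood exactly consistent with the dense oracle.

## Tunable parameters

- **`d` (number of spatial PCs, default 20).** The conventional number of
  low-dimensional components carried into clustering and trajectory work.
- **`gamma` (kernel bandwidth, squared scaled-coordinate units).** Derived
  from the expression data: one bandwidth per gene on its standardized
  expression vector — Silverman's rule $0.9\min(\hat\sigma,
  \mathrm{IQR}/1.34)n^{-1/5}$ for $n > 5000$, the Sheather–Jones
  solve-the-equation plug-in otherwise (robust at small $n$; genes where the
  root-finder fails are skipped) — with the median across genes used as
  $\gamma$. Because this bandwidth is computed on expression values yet
  applied to spatial distances, coordinates are always centered and scaled
  to unit SD per axis before kernel construction; this is the only reading
  that makes the units commensurable, and it also makes CHAOS/PAS/LISI
  comparable across platforms. The scaling record is kept for inverse
  mapping.
- **`variance_threshold` (default 0.90).** The kernel eigendecomposition is
  truncated at the smallest rank whose cumulative eigenvalue fraction
  reaches the threshold; negative eigenvalues (numerical jitter) are clipped
  to zero first.
- **`sparse_cutoff` (default 1e-20).** Kernel entries below the cutoff are
  zeroed; at the default this perturbs no eigenvalue by more than
  $n \times 10^{-20}$.
- **`knn_k` (default 10).** Neighborhood size for both the SNN and KNN
  clustering graphs; SNN edge weights are
  $|\text{shared}|/(2k - |\text{shared}|)$ with zero-weight edges dropped.
  Louvain's resolution is bisected over $[0.01, 5]$ (at most 50 attempts) to
  reach the requested domain count; the Walktrap dendrogram is cut directly.
- **Refinement neighbor count (4 for square ST lattices, 6 for Visium).**
  A single pass of strict-majority relabeling against the pre-pass labels;
  iterating to a fixed point was considered and rejected as it can erase
  genuine thin structures, and a single pass already guarantees (and the
  tests assert) that the abnormal-spot score cannot increase.
- **LISI perplexity (default 30), PAS neighbors 10 / threshold 6, CHAOS 1NN
  edges, Moran's I k = 10 row-normalized weights** — the conventional
  settings for these spatial clustering metrics.
- **Imputation `jitter` (default `1e-8 * mean(diag K)`).** Ridge for the
  kernel solve in $\tilde Z = Z (K + \epsilon I)^{-1} K(s, \tilde s)$; with
  full-rank $K$ and $\epsilon = 0$, imputing at measured locations
  reproduces $Z$ exactly (asserted to $10^{-8}$). The $\sigma_0^2\tau$
  prefactors of the prior covariance cancel in the conditional mean.
- **Subspot geometries.** `st9` splits each square-lattice spot into a 3 × 3
  grid (offsets $\pm e/3$ with $e$ the median nearest-neighbor distance);
  `generic4` places four corners at $\pm e/4$; `visium6` uses two columns
  ($x = \pm e/4$) of three rows ($y \in \{-e/3, 0, e/3\}$) — the six-subspot
  count is fixed by the hexagonal platform layout but the exact offsets are
  a documented constant table of this package. New locations outside the
  convex hull of measured spots are dropped (boundary points kept):
  imputation is interpolation, not extrapolation.

## Normalization

The package accepts pre-normalized input and otherwise applies per-location
total-count scaling to 10,000 followed by `log1p`, then per-gene
standardization. Variance-stabilizing transformations from external toolkits
can be applied upstream and passed in as `state = "normalized"`; the
constant 10,000 is the scRNA-seq convention and only shifts per-gene
intercepts that standardization removes anyway. Missing values are rejected
rather than imputed; zero-count locations and zero-variance genes are
dropped with warnings.

## The synthetic-tissue generator

The simulator emulates a layered cortical tissue: cells are sampled without
replacement from a pixel lattice (default conditions used throughout the
tests: 100 × 100 lattice); `bands4` divides it into four equal-area parallel
bands, `stripes6` into six equal stripes mapped alternately onto two
domains (a deliberately non-contiguous pattern). Cell types 1–4 are drawn
per cell from a multinomial whose composition depends on the domain: the
dominance order rotates across layers (1,2,3,4 / 2,3,4,1 / 3,4,1,2 /
4,1,2,3) and the ranked proportions are set by scenario — S1 70/10/10/10,
S2 45/45/5/5, S3 60/30/5/5, S4 35/30/30/5, and stripe scenarios 60/40,
60/30/5/5, 60/20/20. Counts follow a splat-style gamma–Poisson hierarchy:
gene base means Gamma(shape 0.6, rate 0.3); within each group a `de_prob`
(default 0.5) fraction of genes receives a log-normal multiplicative DE
factor (location 0.1, scale 0.4; up or down with equal probability);
per-cell library sizes log-normal(11, 0.2); Poisson counts around
library × expression proportion. These constants are package defaults
chosen to give realistic single-cell count depth and fold-change spread; a
`params` hook accepts values estimated from an empirical reference instead.
Cells are aggregated on a square grid into subspots (majority-label truth),
merged 3 × 3 into spots (coordinate from the center subspot), and an
optional cell-split step removes a subset of cells and redistributes their
counts to their four nearest surviving neighbors with Dirichlet-uniform
weights via multinomial allocation, conserving total counts exactly.

What the generator does **not** emulate: real tissue geometry (bands replace
a manually segmented cortical image), empirical gene-level parameters
(constants replace estimates from a reference scRNA-seq data set), platform
artifacts (no zero-inflation beyond the gamma–Poisson, no spatial library
gradients, no segmentation errors). Passing tests on these simulations
therefore demonstrates correctness of the algorithms and the direction and
rough magnitude of the spatial-vs-ordinary PCA advantage, not the exact
clustering accuracies attainable on any real platform.

The scaled-down headline experiment in the test suite uses 2,000 cells,
1,000 genes and ~289 spots over five seeds — sizes chosen so the whole suite
runs comfortably on one CPU — and asserts that spatial PCs beat ordinary
PCs by an ARI margin of at least 0.15 with lower CHAOS and PAS; in practice
the observed margin is around 0.3–0.4.

## Numerical choices and degenerate inputs

Loadings have a deterministic sign (largest-magnitude entry of each column
positive), so fits are reproducible to sign. Constant coordinate axes,
rank-deficient covariates, all-singleton clusterings, constant metric inputs
and unreachable cluster counts raise explicit errors naming the offending
quantity. The LISI neighborhood-weight calibration bisects the kernel width
to entropy tolerance $10^{-5}$ and skips (with a warning) spots where it
fails. The local inverse Simpson index is computed as
$1/\sum_k p(k)^2$ — the inverse Simpson form of the published effective
label number (a printed formula without the square would be identically 1).
Silhouette-based cluster-number choice evaluates candidates in PC space and
breaks ties toward fewer clusters; candidates that yield singleton clusters
are skipped.

## Known limitations

- **The null does not force $\tau$ to zero.** Under pure iid noise the
  profile maximum-likelihood $\tau$ stays finitely positive: chance
  alignment of noise with smooth kernel eigendirections always buys a little
  likelihood, exactly as sample covariance top eigenvalues always exceed
  the noise level in PPCA. $\tau$ is therefore a relative, not an absolute,
  spatial-signal diagnostic; the tests discriminate signal from null by the
  per-datum likelihood gain and by the orders-of-magnitude gap in fitted
  $\tau$.
- **Subspace recovery is information-limited.** At moderate gene counts the
  largest principal angle between fitted and true loading subspaces tracks
  the oracle-PCA error (spiked-covariance theory:
  $\sin\theta \approx \sqrt{(m/n)\,(1+\tau)/\tau^2}$ per direction, of which
  the largest of $d$ angles is the worst); the fit is asserted to match that
  baseline, not to beat it.
- The Gaussian likelihood on standardized values is a working approximation
  for counts; count-likelihood variants are out of scope.
- Imputation provides conditional means only (no posterior variances), and
  only inside the convex hull of the measured tissue.
- Pseudo-time is consumed, never inferred: trajectory arrow grids summarize
  an externally supplied ordering.
- The multi-sample block-diagonal kernel assumes sections have been placed
  on a common expression manifold upstream (batch integration is out of
  scope); it models zero a-priori correlation across sections.
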