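# sppca — spatially aware probabilistic PCA for spatial transcriptomics

Spatial transcriptomics measures genome-wide expression at known tissue
locations, and most downstream questions — which spatial domains make up the
tissue, how expression progresses across it — hinge on a good low-dimensional
representation of the gene × location matrix. Ordinary PCA ignores where the
measurements were taken; `sppca` implements a probabilistic PCA in which the
latent factors themselves carry a Gaussian-process prior over the tissue, so
the inferred components ("spatial PCs") borrow strength across neighboring
locations and yield spatially coherent domains. The package is aimed at
analysts of spot- or bead-level platforms (ST, Visium, Slide-seq) and at
method developers who need its evaluation statistics and simulation
framework.

## Model

For an m × n standardized expression matrix **Y** on locations s₁…sₙ with
covariates **X** (intercept by default):

    Y = (XB)ᵀ + WZ + E,      E_ji ~ N(0, σ₀²)

with an orthonormality constraint WᵀW = I_d on the m × d loadings, and each
factor row given a spatial prior

    Z_l· ~ MVN(0, σ₀² τ K),    K(s_i, s_j) = exp(−|s_i − s_j|² / γ).

The bandwidth γ is derived from the expression data (per-gene Silverman rule
for n > 5000, Sheather–Jones otherwise; median across genes). Integrating out
**B** and **Z** gives a marginal likelihood that is maximized over
(W, τ, σ₀²) in the eigenbasis of a low-rank approximation of **K** (smallest
rank keeping ≥ 90% of the kernel variance): for each candidate τ the optimal
W is the top-d eigenvector set of Y·U·diag(τλ/(1+τλ))·Uᵀ·Yᵀ, σ₀² has a
closed-form profile, and τ is found by a 1-D search. The spatial PCs are the
posterior means E[Z | Y]. The same machinery yields kriging-style imputation
of the PCs (and hence expression) on unmeasured subspot locations.

Around the core model the package provides spatial-domain detection (Walktrap
on an SNN graph or Louvain on a KNN graph, silhouette-based cluster-number
choice, majority-rule spatial label refinement), evaluation statistics (ARI,
NMI, CHAOS, PAS, LISI, McFadden-adjusted pseudo-R², metagene enrichment,
Moran's I), a synthetic layered-tissue simulator with gamma–Poisson counts,
and RGB / trajectory-arrow visualization summaries.

## Worked example

Simulate a four-layer cortical tissue (scenario S2: two dominant cell types
per layer at 45%/45%), aggregate single cells into ST-style spots, fit 20
spatial PCs, and detect four spatial domains:

```r
library(sppca)

tissue <- make_layered_tissue(2000, lattice = c(100L, 100L),
                              layout = "bands4", seed = 11)
tissue <- assign_cell_types(tissue, "S2", seed = 12)
tissue <- simulate_tissue_counts(tissue, 1000, seed = 13)
tissue <- aggregate_to_spots(tissue, grid_edge = 2)
tissue
#> SyntheticTissue: 2000 cells on a 100 x 100 lattice (bands4, 4 domains)
#>   counts: 1000 genes
#>   aggregated: 2601 subspots, 289 spots

expr   <- expression_matrix(tissue$spot_counts, state = "counts")
coords <- spatial_coordinates(tissue$spot_coords)
fit <- spatial_pca(expr, coords, d = 20)
fit
#> SpatialPCAFit: 990 genes, 289 locations, 20 factors
#>   tau = 25.96, sigma0^2 = 0.619, loglik = -339160.4417

domains <- cluster_pcs(fit$Z, "walktrap_snn", target_clusters = 4, seed = 11)
domains <- refine_labels(domains, fit$kernel$coords, neighbor_count = 6)

truth <- tissue$spot_labels[match(fit$expr$location_ids,
                                  colnames(tissue$spot_counts))]
ari(domains$labels, truth)
#> [1] 0.838
chaos(domains$labels, fit$kernel$coords)
#> [1] 0.204
pas(domains$labels, fit$kernel$coords)
#> [1] 0.0104
```

The large fitted `tau` (≈ 26) says the factors are dominated by spatial
variance relative to residual noise; the detected domains recover the true
layers closely (ARI 0.84) and are spatially smooth (PAS ≈ 1%, i.e. almost no
spot disagrees with the bulk of its neighborhood). On the same data, ordinary
PCA followed by the identical clustering typically reaches ARI ≈ 0.4–0.55.

A command-line front end with `fit`, `impute`, `cluster`, `metrics`,
`simulate` and `summarize` subcommands is installed at
`system.file("cli", "sppca.R", package = "sppca")`.

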