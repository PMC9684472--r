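# Visualization-ready summaries: RGB embedding statistics and tissue
# trajectory arrow grids.

minmax01 <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(0, length(x)))
  (x - rng[1]) / diff(rng)
}

#' Weighted RGB summary of the embedding
#'
#' Summarizes the spatial PCs into three components (UMAP, tSNE, or simply the
#' first three factors), min-max scales each component to [0, 1] as the R/G/B
#' channels, and computes the variance-weighted scalar summary
#' `RGB_weighted = (R*var(R) + G*var(G) + B*var(B)) / (var(R)+var(G)+var(B))`,
#' standardized to mean 0 / SD 1. The per-location neighborhood variance is
#' the sample variance of the standardized weighted values over each location
#' and its six nearest neighbors; small values indicate a spatially smooth
#' embedding.
#'
#' @param Z d x n matrix of spatial PCs (d >= 3).
#' @param embed `"first3"` (deterministic; default), `"umap3"` or `"tsne3"`
#'   (require the uwot / Rtsne packages).
#' @param coords `SpatialCoordinates` for the neighborhood variance.
#' @param seed integer seed for the stochastic embeddings.
#'
#' @return An object of class `RgbSummary`: list with `rgb` (n x 3 in [0,1]),
#'   `weighted` (standardized), `neighborhood_variance`.
#' @export
rgb_summary <- function(Z, embed = c("first3", "umap3", "tsne3"), coords,
                        seed = 1L) {
  embed <- match.arg(embed)
  Z <- as.matrix(Z)
  if (nrow(Z) < 3) stop("need at least 3 factors for an RGB summary")
  stopifnot(inherits(coords, "SpatialCoordinates"))
  x <- t(Z)
  emb <- switch(embed,
    first3 = x[, 1:3, drop = FALSE],
    umap3 = {
      if (!requireNamespace("uwot", quietly = TRUE))
        stop("embed = 'umap3' requires the uwot package")
      set.seed(seed)
      uwot::umap(x, n_components = 3)
    },
    tsne3 = {
      if (!requireNamespace("Rtsne", quietly = TRUE))
        stop("embed = 'tsne3' requires the Rtsne package")
      set.seed(seed)
      Rtsne::Rtsne(x, dims = 3, pca = FALSE,
                   perplexity = min(30, floor((nrow(x) - 1) / 3)))$Y
    })
  rgbm <- apply(emb, 2, minmax01)
  colnames(rgbm) <- c("R", "G", "B")
  v <- apply(rgbm, 2, stats::var)
  if (sum(v) == 0) stop("degenerate embedding: all components constant")
  weighted <- as.vector(rgbm %*% v) / sum(v)
  weighted <- as.vector(scale(weighted))
  nn <- FNN::get.knn(coords$coords, k = min(6, nrow(coords$coords) - 1))$nn.index
  nv <- vapply(seq_len(nrow(rgbm)), function(i)
    stats::var(weighted[c(i, nn[i, ])]), 1)
  structure(list(rgb = rgbm, weighted = weighted,
                 neighborhood_variance = nv, embed = embed),
            class = "RgbSummary")
}

#' Trajectory arrows on a square grid
#'
#' Overlays the tissue with an evenly spaced square grid; in every grid cell
#' containing at least two locations with non-constant pseudo-time, an arrow
#' is drawn from the minimum-pseudo-time location to the maximum. The grid
#' size is the smallest candidate for which at least one third of the arrows
#' cross a domain boundary (start and end in different domains); if no
#' candidate qualifies, the largest is used with a warning.
#'
#' @param pseudotime per-location pseudo-time values (supplied by an external
#'   trajectory method).
#' @param labels a `DomainLabeling` (or integer label vector).
#' @param coords `SpatialCoordinates`.
#' @param grid_candidates candidate grid sizes, cells per axis
#'   (default `c(10, 15, 20, 25, 30)`).
#'
#' @return List with `arrows` (data.frame x0, y0, x1, y1, from_domain,
#'   to_domain), `grid_size`, `cross_fraction`.
#' @export
trajectory_arrows <- function(pseudotime, labels, coords,
                              grid_candidates = c(10, 15, 20, 25, 30)) {
  stopifnot(inherits(coords, "SpatialCoordinates"))
  if (inherits(labels, "DomainLabeling")) labels <- labels$labels
  m <- coords$coords
  if (length(pseudotime) != nrow(m)) stop("pseudotime length mismatch")
  if (stats::sd(pseudotime) == 0) {
    warning("all pseudo-time values equal: no arrows")
    return(list(arrows = NULL, grid_size = NA_integer_,
                cross_fraction = NA_real_))
  }
  build <- function(gs) {
    cx <- pmin(floor((m[, 1] - min(m[, 1])) / (diff(range(m[, 1])) / gs)), gs - 1)
    cy <- pmin(floor((m[, 2] - min(m[, 2])) / (diff(range(m[, 2])) / gs)), gs - 1)
    cell <- paste(cx, cy, sep = "_")
    rows <- lapply(unique(cell), function(cl) {
      idx <- which(cell == cl)
      if (length(idx) < 2) return(NULL)
      pt <- pseudotime[idx]
      if (max(pt) == min(pt)) return(NULL)
      i0 <- idx[which.min(pt)]; i1 <- idx[which.max(pt)]
      data.frame(x0 = m[i0, 1], y0 = m[i0, 2], x1 = m[i1, 1], y1 = m[i1, 2],
                 from_domain = labels[i0], to_domain = labels[i1])
    })
    do.call(rbind, rows)
  }
  chosen <- NULL; gs_used <- NA_integer_; frac <- NA_real_
  for (gs in sort(grid_candidates)) {
    arr <- build(gs)
    if (is.null(arr)) next
    f <- mean(arr$from_domain != arr$to_domain)
    if (is.null(chosen)) { chosen <- arr; gs_used <- gs; frac <- f }
    if (f >= 1 / 3) { chosen <- arr; gs_used <- gs; frac <- f; break }
    chosen <- arr; gs_used <- gs; frac <- f
  }
  if (is.null(chosen)) {
    warning("no grid cell produced an arrow")
    return(list(arrows = NULL, grid_size = NA_integer_,
                cross_fraction = NA_real_))
  }
  if (frac < 1 / 3)
    warning("no candidate grid reached 1/3 cross-domain arrows; using the largest")
  rownames(chosen) <- NULL
  list(arrows = chosen, grid_size = gs_used, cross_fraction = frac)
}
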