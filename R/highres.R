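# High-resolution reconstruction: subspot geometries and kriging-style
# imputation of spatial PCs / expression on unmeasured locations.

# signed-area test: point inside or on the convex hull of pts (2D)
in_convex_hull <- function(points, pts, tol = 1e-9) {
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  nh <- nrow(hull)
  inside <- rep(TRUE, nrow(points))
  # chull returns clockwise order; orient consistently via signed area
  area2 <- sum(hull[, 1] * hull[c(2:nh, 1), 2] - hull[c(2:nh, 1), 1] * hull[, 2])
  sgn <- if (area2 >= 0) 1 else -1
  for (e in seq_len(nh)) {
    a <- hull[e, ]; b <- hull[if (e == nh) 1 else e + 1, ]
    cr <- sgn * ((b[1] - a[1]) * (points[, 2] - a[2]) -
                   (b[2] - a[2]) * (points[, 1] - a[1]))
    inside <- inside & (cr >= -tol)
  }
  inside
}

median_nn_distance <- function(m) {
  nn <- FNN::get.knn(m, k = 1)
  stats::median(nn$nn.dist[, 1])
}

#' Generate subspot locations for high-resolution maps
#'
#' Creates new, unmeasured locations inside each measured spot following the
#' platform lattice: `st9` splits each square-lattice ST spot into a 3 x 3
#' grid of nine subspots; `visium6` splits each hexagonal-lattice spot into
#' six subspots (two offset columns of three); `generic4` places four new
#' locations at the corners of a square centered on the spot, at offsets
#' +/- delta on each axis with `delta = 1/4` of the median nearest-neighbor
#' distance. New locations outside the convex hull of the measured locations
#' are dropped with a warning (imputation is only performed where surrounded
#' by observed expression); locations on the hull boundary are kept.
#'
#' @param coords scaled 2D [spatial_coordinates()] of the measured spots.
#' @param geometry `"st9"`, `"visium6"` or `"generic4"`.
#'
#' @return An object of class `NewLocations`: list with `coords` (scaled
#'   coordinates of the new locations), `parent` (index of the source spot)
#'   and `geometry`.
#' @export
make_subspot_locations <- function(coords, geometry = c("generic4", "st9", "visium6")) {
  stopifnot(inherits(coords, "SpatialCoordinates"))
  if (!coords$scaled) stop("make_subspot_locations expects scaled coordinates")
  geometry <- match.arg(geometry)
  m <- coords$coords
  if (nrow(m) < 2) stop("need at least 2 measured locations")
  if (ncol(m) != 2) stop("subspot geometries are defined for 2D coordinates")
  e <- median_nn_distance(m)
  offsets <- switch(geometry,
    generic4 = {
      d <- e / 4
      cbind(c(-d, -d, d, d), c(-d, d, -d, d))
    },
    st9 = as.matrix(expand.grid(x = c(-1, 0, 1) * e / 3,
                                y = c(-1, 0, 1) * e / 3)),
    visium6 = as.matrix(expand.grid(x = c(-1, 1) * e / 4,
                                    y = c(-1, 0, 1) * e / 3)))
  ns <- nrow(offsets)
  new <- m[rep(seq_len(nrow(m)), each = ns), , drop = FALSE] +
    offsets[rep(seq_len(ns), times = nrow(m)), , drop = FALSE]
  parent <- rep(seq_len(nrow(m)), each = ns)
  keep <- in_convex_hull(new, m)
  if (!all(keep))
    warning(sprintf("dropping %d subspot(s) outside the measured convex hull",
                    sum(!keep)))
  new <- new[keep, , drop = FALSE]
  parent <- parent[keep]
  rownames(new) <- sprintf("%s_sub%d", rownames(m)[parent],
                           as.integer(stats::ave(parent, parent, FUN = seq_along)))
  structure(list(coords = spatial_coordinates(new, scaled = TRUE),
                 parent = parent, geometry = geometry),
            class = "NewLocations")
}

#' User-supplied new locations
#'
#' Wraps arbitrary coordinates as imputation targets; points outside the
#' convex hull of the measured locations are dropped with a warning.
#'
#' @param coords scaled `SpatialCoordinates` of the new locations.
#' @param measured scaled `SpatialCoordinates` of the measured locations.
#' @return A `NewLocations` object with `geometry = "user"`.
#' @export
new_locations <- function(coords, measured) {
  stopifnot(inherits(coords, "SpatialCoordinates"),
            inherits(measured, "SpatialCoordinates"))
  keep <- in_convex_hull(coords$coords, measured$coords)
  if (!all(keep))
    warning(sprintf("dropping %d location(s) outside the measured convex hull",
                    sum(!keep)))
  structure(list(coords = spatial_coordinates(
    coords$coords[keep, , drop = FALSE], scaled = TRUE),
    parent = NULL, geometry = "user"),
    class = "NewLocations")
}

#' Impute spatial PCs on new locations
#'
#' Kriging-style conditional mean of the latent factors at unmeasured
#' locations: `Z~ = Z [K + jitter I]^{-1} K(s, s~)` per factor, where the
#' cross-kernel uses the fitted bandwidth on the scaled coordinates. The
#' `sigma0^2 * tau` prior prefactors cancel. With `jitter = 0` and a
#' full-rank kernel, imputing at the measured locations returns the spatial
#' PCs exactly.
#'
#' @param fit a `SpatialPCAFit` whose kernel is Gaussian.
#' @param new a `NewLocations` object.
#' @param jitter non-negative ridge added to the kernel diagonal for the
#'   solve; default `1e-8 * mean(diag(K))`.
#' @return The d x n-new matrix of imputed spatial PCs.
#' @export
impute_spatial_pcs <- function(fit, new, jitter = NULL) {
  stopifnot(inherits(fit, "SpatialPCAFit"), inherits(new, "NewLocations"))
  kern <- fit$kernel
  if (kern$kind != "gaussian")
    stop("imputation requires a kernel reproducible at new coordinates (gaussian)")
  K <- kern$K
  if (is.null(jitter)) jitter <- 1e-8 * mean(diag(K))
  s <- kern$coords$coords
  st <- new$coords$coords
  cross <- exp(-outer(rowSums(s^2), rowSums(st^2), "+") / kern$gamma +
                 (2 / kern$gamma) * (s %*% t(st)))
  A <- K + diag(jitter, nrow(K))
  sol <- tryCatch(solve(A, cross), error = function(e)
    stop("kernel system is singular; retry with a positive jitter"))
  Zt <- fit$Z %*% sol
  colnames(Zt) <- rownames(st)
  Zt
}

#' Predict expression on new locations
#'
#' Posterior-mean expression at imputed locations: the product of the fitted
#' loading matrix and the imputed spatial PCs, `Y~ = W Z~`, on the
#' standardized scale of the training data.
#'
#' @param fit a `SpatialPCAFit`.
#' @param imputed d x n-new matrix from [impute_spatial_pcs()].
#' @param genes optional character vector restricting the output genes.
#' @return A gene x n-new matrix of predicted standardized expression.
#' @export
predict_expression <- function(fit, imputed, genes = NULL) {
  stopifnot(inherits(fit, "SpatialPCAFit"))
  if (nrow(imputed) != fit$d) stop("imputed factors must have d rows")
  W <- fit$W
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(W))
    if (length(missing))
      stop("unknown gene(s): ", paste(missing, collapse = ", "))
    W <- W[genes, , drop = FALSE]
  }
  W %*% imputed
}
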