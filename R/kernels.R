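#' Spatial coordinates container
#'
#' Holds location coordinates (2D or 3D) together with the centering/scaling
#' record needed to map between platform units and the scaled coordinates on
#' which all kernels are built.
#'
#' @param coords location x k numeric matrix, k in {2, 3}.
#' @param scaled logical; whether each axis already has mean 0, SD 1.
#' @param axis_means,axis_sds per-axis scaling record (used by
#'   [unscale_coordinates()]).
#'
#' @return An object of class `SpatialCoordinates`.
#' @export
spatial_coordinates <- function(coords, scaled = FALSE,
                                axis_means = NULL, axis_sds = NULL) {
  coords <- as.matrix(coords)
  if (!ncol(coords) %in% c(2L, 3L)) stop("coordinates must be 2D or 3D")
  if (anyNA(coords) || any(!is.finite(coords)))
    stop("non-finite coordinates are rejected")
  if (is.null(rownames(coords)))
    rownames(coords) <- paste0("loc", seq_len(nrow(coords)))
  structure(list(coords = coords, scaled = scaled,
                 axis_means = axis_means, axis_sds = axis_sds),
            class = "SpatialCoordinates")
}

#' @export
print.SpatialCoordinates <- function(x, ...) {
  cat(sprintf("SpatialCoordinates: %d locations x %d axes (%s)\n",
              nrow(x$coords), ncol(x$coords),
              if (x$scaled) "scaled" else "platform units"))
  invisible(x)
}

#' Center and scale coordinates
#'
#' Each axis is centered and scaled to unit sample SD. The expression-derived
#' kernel bandwidth is on the scale of standardized expression values, so
#' coordinates are brought onto a comparable unit-variance scale before any
#' kernel is built. Scaling an already-scaled object is a no-op.
#'
#' @param coords a [spatial_coordinates()] object.
#' @return The scaled `SpatialCoordinates`, with the scaling record retained.
#' @export
scale_coordinates <- function(coords) {
  stopifnot(inherits(coords, "SpatialCoordinates"))
  if (coords$scaled) return(coords)
  m <- coords$coords
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  if (any(sdv == 0)) stop("constant coordinate axis: degenerate geometry")
  s <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  spatial_coordinates(s, scaled = TRUE, axis_means = mu, axis_sds = sdv)
}

#' Invert coordinate scaling
#'
#' @param coords a scaled `SpatialCoordinates` with a scaling record.
#' @return The coordinates in the original platform units.
#' @export
unscale_coordinates <- function(coords) {
  stopifnot(inherits(coords, "SpatialCoordinates"))
  if (!coords$scaled) return(coords)
  if (is.null(coords$axis_means)) stop("no scaling record to invert")
  m <- sweep(sweep(coords$coords, 2, coords$axis_sds, "*"), 2,
             coords$axis_means, "+")
  spatial_coordinates(m, scaled = FALSE)
}

silverman_bw <- function(x) {
  n <- length(x)
  0.9 * min(stats::sd(x), stats::IQR(x) / 1.34) * n^(-1 / 5)
}

#' Select the kernel bandwidth from expression spread
#'
#' The Gaussian-kernel bandwidth gamma is computed from the expression data in
#' a sample-size-dependent fashion: one bandwidth per gene on that gene's
#' standardized expression vector, with the median across genes returned. For
#' large samples (n > 5000) the Silverman rule-of-thumb
#' `0.9 * min(sd, IQR/1.34) * n^(-1/5)` is used; for smaller samples the
#' Sheather-Jones solve-the-equation plug-in estimator. Genes on which the
#' estimator fails (e.g. heavily tied vectors) are skipped.
#'
#' @param expr a standardized `ExpressionMatrix`.
#' @param n number of spatial locations (defaults to the column count).
#' @param method `"auto"` (Silverman if n > 5000, else Sheather-Jones),
#'   `"silverman"`, or `"sheather_jones"`.
#'
#' @return The bandwidth gamma (positive scalar, squared-coordinate units).
#' @export
select_bandwidth <- function(expr, n = ncol(expr$values),
                             method = c("auto", "silverman", "sheather_jones")) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$state != "standardized")
    stop("select_bandwidth expects standardized expression")
  method <- match.arg(method)
  if (method == "auto")
    method <- if (n > 5000) "silverman" else "sheather_jones"
  est <- if (method == "silverman") silverman_bw else
    function(x) stats::bw.SJ(x, method = "ste")
  bw <- apply(expr$values, 1, function(x) {
    tryCatch(est(x), error = function(e) NA_real_)
  })
  bw <- bw[is.finite(bw) & bw > 0]
  if (!length(bw)) stop("no gene yielded a finite positive bandwidth")
  stats::median(bw)
}

#' Build a Gaussian spatial kernel
#'
#' Constructs the n x n spatial covariance kernel
#' `K_ij = exp(-d^2_ij / gamma)` over the scaled coordinates, where `d^2` is
#' the squared Euclidean distance, optionally augmented by standardized
#' histology pseudo-dimensions appended to the coordinates. Entries below
#' `sparse_cutoff` are set to zero.
#'
#' @param coords scaled [spatial_coordinates()].
#' @param gamma positive bandwidth (see [select_bandwidth()]).
#' @param sparse_cutoff entries below this value are zeroed (default 1e-20).
#' @param histology optional location x h numeric matrix of image-derived
#'   features; each column is z-scored and appended as a pseudo-dimension of
#'   the distance.
#'
#' @return An object of class `SpatialKernel` with elements `K`, `gamma`,
#'   `coords`, `kind = "gaussian"`; eigenpairs are added by
#'   [lowrank_eigen()].
#' @export
build_kernel <- function(coords, gamma, sparse_cutoff = 1e-20,
                         histology = NULL) {
  stopifnot(inherits(coords, "SpatialCoordinates"))
  if (!coords$scaled) stop("build_kernel expects scaled coordinates")
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be positive and finite")
  m <- coords$coords
  if (!is.null(histology)) {
    histology <- as.matrix(histology)
    if (nrow(histology) != nrow(m))
      stop("histology must have one row per location")
    histology <- scale(histology)
    m <- cbind(m, histology)
  }
  d2 <- as.matrix(stats::dist(m))^2
  if (any(!is.finite(d2))) stop("non-finite distance encountered")
  K <- exp(-d2 / gamma)
  K[K < sparse_cutoff] <- 0
  K <- (K + t(K)) / 2
  diag(K) <- 1
  new_kernel(K, gamma = gamma, coords = coords, kind = "gaussian",
             histology = histology)
}

new_kernel <- function(K, gamma = NA_real_, coords = NULL, kind = "gaussian",
                       histology = NULL) {
  structure(list(K = K, gamma = gamma, coords = coords, kind = kind,
                 histology = histology,
                 eigvecs = NULL, eigvals = NULL, rank = NULL,
                 variance_fraction = NULL),
            class = "SpatialKernel")
}

#' @export
print.SpatialKernel <- function(x, ...) {
  cat(sprintf("SpatialKernel (%s): %d locations", x$kind, nrow(x$K)))
  if (!is.null(x$rank))
    cat(sprintf(", rank %d (%.1f%% variance)", x$rank,
                100 * x$variance_fraction))
  cat("\n")
  invisible(x)
}

#' Delaunay hop-distance matrix
#'
#' Computes, for 2D locations, the minimum number of edges one must travel
#' between each pair of locations on the Delaunay triangulation graph (two
#' locations are neighbors when their Voronoi polygons share an edge). The
#' hop distance can be substituted for the Euclidean distance in the Gaussian
#' kernel via [delaunay_kernel()].
#'
#' @param coords a 2D [spatial_coordinates()] object with at least 3
#'   non-collinear points.
#' @return A symmetric integer n x n matrix of shortest-path hop counts.
#' @export
delaunay_distance_matrix <- function(coords) {
  stopifnot(inherits(coords, "SpatialCoordinates"))
  m <- coords$coords
  if (ncol(m) != 2) stop("Delaunay distances require 2D coordinates")
  if (nrow(m) < 3) stop("need at least 3 points")
  tri <- deldir::deldir(m[, 1], m[, 2], suppressMsge = TRUE)
  e <- tri$delsgs[, c("ind1", "ind2")]
  g <- igraph::graph_from_edgelist(as.matrix(e), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(m) - igraph::vcount(g)))
  D <- igraph::distances(g)
  if (any(!is.finite(D)))
    stop("Delaunay graph is disconnected (degenerate geometry)")
  storage.mode(D) <- "integer"
  dimnames(D) <- list(rownames(m), rownames(m))
  D
}

#' Gaussian kernel on Delaunay hop distances
#'
#' @param coords a 2D scaled [spatial_coordinates()] object.
#' @param gamma positive bandwidth applied to squared hop counts.
#' @param sparse_cutoff entries below this value are zeroed.
#' @return A `SpatialKernel` with `kind = "delaunay"`.
#' @export
delaunay_kernel <- function(coords, gamma, sparse_cutoff = 1e-20) {
  D <- delaunay_distance_matrix(coords)
  K <- exp(-(D^2) / gamma)
  K[K < sparse_cutoff] <- 0
  diag(K) <- 1
  new_kernel(K, gamma = gamma, coords = coords, kind = "delaunay")
}

#' Low-rank eigendecomposition of a kernel
#'
#' Retains the smallest number of leading eigenpairs whose cumulative
#' eigenvalue fraction reaches `variance_threshold` (default 0.90). Negative
#' eigenvalues (numerical jitter) are clipped to zero before the fraction is
#' computed. The retained eigenpairs drive all likelihood computations.
#'
#' @param kernel a `SpatialKernel`.
#' @param variance_threshold fraction of kernel variance to retain, in (0, 1].
#' @return The kernel with `eigvecs`, `eigvals`, `rank` and
#'   `variance_fraction` filled in.
#' @export
lowrank_eigen <- function(kernel, variance_threshold = 0.9) {
  stopifnot(inherits(kernel, "SpatialKernel"))
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("variance_threshold must be in (0, 1]")
  ev <- eigen(kernel$K, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  total <- sum(vals)
  frac <- cumsum(vals) / total
  r <- which(frac >= variance_threshold - 1e-12)[1]
  if (is.na(r)) r <- length(vals)
  kernel$eigvals <- vals[seq_len(r)]
  kernel$eigvecs <- ev$vectors[, seq_len(r), drop = FALSE]
  kernel$rank <- r
  kernel$variance_fraction <- frac[r]
  kernel
}

#' Block-diagonal kernel over multiple tissue sections
#'
#' Joins per-sample kernels into one block-diagonal kernel over the
#' concatenated locations: locations within a section keep their spatial
#' correlation, locations across sections are a priori uncorrelated. The
#' eigenpairs are the union of the per-block eigenpairs, re-sorted in
#' descending order.
#'
#' @param per_sample list of two or more `SpatialKernel` objects with
#'   eigenpairs (see [lowrank_eigen()]).
#' @return A `SpatialKernel` with `kind = "block"`.
#' @export
block_kernel <- function(per_sample) {
  if (length(per_sample) < 2) stop("need at least 2 samples")
  stopifnot(all(vapply(per_sample, inherits, TRUE, "SpatialKernel")))
  if (any(vapply(per_sample, function(k) is.null(k$eigvals), TRUE)))
    stop("run lowrank_eigen() on each sample kernel first")
  ids <- unlist(lapply(per_sample, function(k) rownames(k$K)))
  if (anyDuplicated(ids)) stop("duplicated location ids across samples")
  ns <- vapply(per_sample, function(k) nrow(k$K), 1L)
  n <- sum(ns)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  U <- matrix(0, n, sum(vapply(per_sample, function(k) k$rank, 1L)))
  vals <- numeric(0)
  off_r <- 0L; off_c <- 0L
  for (k in per_sample) {
    idx <- off_r + seq_len(nrow(k$K))
    K[idx, idx] <- k$K
    U[idx, off_c + seq_len(k$rank)] <- k$eigvecs
    vals <- c(vals, k$eigvals)
    off_r <- off_r + nrow(k$K)
    off_c <- off_c + k$rank
  }
  o <- order(vals, decreasing = TRUE)
  out <- new_kernel(K, gamma = per_sample[[1]]$gamma, coords = NULL,
                    kind = "block")
  out$eigvals <- vals[o]
  out$eigvecs <- U[, o, drop = FALSE]
  out$rank <- length(vals)
  # fraction is inherited from the per-block truncations
  ev_tot <- sum(vapply(per_sample, function(k)
    sum(k$eigvals) / k$variance_fraction, 1))
  out$variance_fraction <- sum(vals) / ev_tot
  out
}
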