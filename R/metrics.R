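# Evaluation statistics for spatial clustering: ARI, NMI, CHAOS, PAS, LISI,
# McFadden-adjusted pseudo-R2, metagene enrichment, Moran's I.

check_labels <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions via the standard
#' contingency-table formula; invariant to label renaming.
#'
#' @param a,b label vectors of equal length.
#' @return ARI (<= 1; 0 in expectation under random labelings).
#' @export
ari <- function(a, b) {
  check_labels(a, b)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(0)
  (sum_ij - expected) / (max_idx - expected)
}

#' Normalized mutual information
#'
#' Mutual information of two partitions normalized by the arithmetic mean of
#' their entropies (0 for a constant labeling pair by convention).
#'
#' @param a,b label vectors of equal length.
#' @return NMI in [0, 1].
#' @export
nmi <- function(a, b) {
  check_labels(a, b)
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha + hb == 0) return(0)
  mi / ((ha + hb) / 2)
}

#' CHAOS: within-cluster 1-nearest-neighbor edge length
#'
#' For each spatial domain, every member location is connected to its nearest
#' same-domain location (one directed edge per location, Euclidean weight on
#' the given coordinates); CHAOS is the total edge length divided by the total
#' location count. Smaller values indicate spatially smoother domains.
#' Singleton domains contribute no edge.
#'
#' @param labels integer domain labels.
#' @param coords `SpatialCoordinates` (conventionally scaled).
#' @return The CHAOS score (>= 0).
#' @export
chaos <- function(labels, coords) {
  stopifnot(inherits(coords, "SpatialCoordinates"))
  m <- coords$coords
  check_labels(labels, seq_len(nrow(m)))
  total <- 0
  any_edge <- FALSE
  for (k in unique(labels)) {
    idx <- which(labels == k)
    if (length(idx) < 2) next
    any_edge <- TRUE
    nn <- FNN::get.knn(m[idx, , drop = FALSE], k = 1)
    total <- total + sum(nn$nn.dist[, 1])
  }
  if (!any_edge) stop("all domains are singletons; CHAOS undefined")
  total / nrow(m)
}

#' PAS: proportion of abnormal spots
#'
#' The fraction of locations whose domain label differs from at least
#' `threshold` of their `k` nearest neighboring locations (self excluded).
#' Smaller values indicate more homogeneous domains.
#'
#' @param labels integer domain labels.
#' @param coords `SpatialCoordinates`.
#' @param k neighborhood size (default 10).
#' @param threshold minimum number of discordant neighbors (default 6).
#' @return PAS in [0, 1].
#' @export
pas <- function(labels, coords, k = 10, threshold = 6) {
  stopifnot(inherits(coords, "SpatialCoordinates"))
  m <- coords$coords
  n <- nrow(m)
  check_labels(labels, seq_len(n))
  if (n <= k) stop("need more locations than neighbors")
  nn <- FNN::get.knn(m, k = k)$nn.index
  disc <- rowSums(matrix(labels[nn], nrow = n) != labels)
  mean(disc >= threshold)
}

# Gaussian-kernel neighbor weights calibrated so the weight entropy equals
# log(perplexity); returns normalized weights (tSNE-style calibration).
calibrate_weights <- function(d2, perplexity, tol = 1e-5, max_iter = 100) {
  target <- log(perplexity)
  lo <- 0; hi <- Inf; beta <- 1
  for (it in seq_len(max_iter)) {
    w <- exp(-d2 * beta)
    sw <- sum(w)
    if (sw < .Machine$double.xmin) { hi <- beta; beta <- (lo + hi) / 2; next }
    p <- w / sw
    h <- -sum(p[p > 0] * log(p[p > 0]))
    if (abs(h - target) < tol) return(p)
    if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2 }
    else { hi <- beta; beta <- (lo + hi) / 2 }
  }
  p
}

#' LISI: local inverse Simpson's index of domain labels
#'
#' For each location, Gaussian-kernel weights over its `3 * perplexity`
#' nearest locations are calibrated so their entropy equals
#' `log(perplexity)`; with `p(k)` the total weight carried by domain `k`, the
#' per-location score is the inverse Simpson index `1 / sum_k p(k)^2` — the
#' effective number of domain labels in the local neighborhood. A score of 1
#' means a locally pure domain.
#'
#' @param labels integer domain labels.
#' @param coords `SpatialCoordinates`.
#' @param perplexity neighborhood perplexity (default 30).
#' @return Numeric vector of per-location LISI scores in [1, C]; the
#'   conventional summary is `median(lisi(...))`.
#' @export
lisi <- function(labels, coords, perplexity = 30) {
  stopifnot(inherits(coords, "SpatialCoordinates"))
  m <- coords$coords
  n <- nrow(m)
  check_labels(labels, seq_len(n))
  k <- min(as.integer(ceiling(3 * perplexity)), n - 1)
  nn <- FNN::get.knn(m, k = k)
  out <- numeric(n)
  for (i in seq_len(n)) {
    p <- calibrate_weights(nn$nn.dist[i, ]^2, perplexity)
    pk <- tapply(p, labels[nn$nn.index[i, ]], sum)
    out[i] <- 1 / sum(pk^2)
  }
  out
}

#' McFadden-adjusted pseudo-R2 of domain predictiveness
#'
#' Fits a multinomial logistic regression of the true domain labels on the
#' given predictors (e.g. low-dimensional components) and returns the
#' McFadden-adjusted pseudo-R2,
#' `1 - (logLik_model - K) / logLik_null`, where `K` is the number of
#' estimated non-intercept parameters and the null model is intercept-only.
#' A small ridge penalty stabilizes separable fits.
#'
#' @param predictors location x p numeric matrix.
#' @param truth true domain labels (>= 2 classes).
#' @param decay ridge penalty passed to the multinomial fit (default 1e-4).
#' @return The adjusted pseudo-R2 (<= 1; near 0 for uninformative predictors).
#' @export
pseudo_r2_mcfadden <- function(predictors, truth, decay = 1e-4) {
  predictors <- as.matrix(predictors)
  truth <- factor(truth)
  if (nlevels(truth) < 2) stop("need at least 2 classes")
  if (nrow(predictors) != length(truth))
    stop("predictors must have one row per location")
  df <- data.frame(.y = truth, predictors)
  cap <- utils::capture.output({
    fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, decay = decay,
                          maxit = 500, MaxNWts = 1e5)
    fit0 <- nnet::multinom(.y ~ 1, data = df, trace = FALSE)
  })
  ll <- -fit$deviance / 2
  ll0 <- -fit0$deviance / 2
  kpar <- ncol(predictors) * (nlevels(truth) - 1)
  1 - (ll - kpar) / ll0
}

#' Metagene enrichment score of detected domains
#'
#' For each true domain: domain-specific up-regulated genes are found by a
#' one-vs-rest rank-sum test on normalized expression (BH-adjusted p below
#' `p_cutoff` and positive fold change); their per-location mean, min-max
#' scaled to [0, 1], is the domain metagene. The detected domain with the
#' highest overlap fraction with the true domain (required >= `overlap_min`)
#' is matched to it, and the score is the ratio of mean metagene expression
#' inside versus outside the matched domain.
#'
#' @param expr an `ExpressionMatrix` (counts are log-normalized internally;
#'   normalized input is used as-is).
#' @param truth true domain labels.
#' @param detected detected domain labels on the same locations.
#' @param overlap_min minimum overlap fraction for a match (default 0.35).
#' @param p_cutoff BH-adjusted p-value threshold for DE genes (default 0.001).
#' @return Named numeric vector of per-true-domain scores (NA when no DE gene
#'   or no sufficiently overlapping detected domain exists).
#' @export
metagene_enrichment <- function(expr, truth, detected, overlap_min = 0.35,
                                p_cutoff = 0.001) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  check_labels(truth, detected)
  if (length(truth) != ncol(expr$values))
    stop("labels must cover the expression locations")
  v <- expr$values
  if (expr$state == "counts") {
    tot <- pmax(colSums(v), 1)
    v <- log1p(sweep(v, 2, tot / 1e4, "/"))
  }
  doms <- sort(unique(truth))
  out <- stats::setNames(rep(NA_real_, length(doms)), as.character(doms))
  for (dm in doms) {
    inside <- truth == dm
    pv <- apply(v, 1, function(x)
      stats::wilcox.test(x[inside], x[!inside], exact = FALSE)$p.value)
    lfc_pos <- rowMeans(v[, inside, drop = FALSE]) >
      rowMeans(v[, !inside, drop = FALSE])
    de <- which(stats::p.adjust(pv, "BH") < p_cutoff & lfc_pos)
    if (!length(de)) next
    meta <- colMeans(v[de, , drop = FALSE])
    rng <- range(meta)
    meta <- if (diff(rng) > 0) (meta - rng[1]) / diff(rng) else rep(1, length(meta))
    overlap <- vapply(sort(unique(detected)), function(dd)
      sum(detected == dd & inside) / sum(inside), 1)
    if (max(overlap) < overlap_min) next
    match_dom <- sort(unique(detected))[which.max(overlap)]
    inside_det <- detected == match_dom
    denom <- mean(meta[!inside_det])
    out[as.character(dm)] <- mean(meta[inside_det]) / denom
  }
  out
}

#' Moran's I spatial autocorrelation
#'
#' Standard Moran's I with row-normalized binary k-nearest-neighbor weights;
#' the expectation under no spatial autocorrelation is `-1/(n-1)`.
#'
#' @param values per-location numeric vector (non-constant).
#' @param coords `SpatialCoordinates`.
#' @param k neighborhood size for the weights (default 10).
#' @return Moran's I (scalar).
#' @export
morans_i <- function(values, coords, k = 10) {
  stopifnot(inherits(coords, "SpatialCoordinates"))
  m <- coords$coords
  n <- nrow(m)
  check_labels(values, seq_len(n))
  if (stats::sd(values) == 0) stop("constant input: Moran's I undefined")
  nn <- FNN::get.knn(m, k = k)$nn.index
  z <- values - mean(values)
  num <- sum(z * rowMeans(matrix(z[nn], nrow = n)))  # row-normalized weights
  s0 <- n                                            # each row sums to 1
  (n / s0) * num / sum(z^2)
}
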