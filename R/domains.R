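# Spatial-domain detection: neighbor graphs on the spatial PCs, community
# detection (Walktrap on an SNN graph, Louvain on a KNN graph), silhouette
# based choice of the cluster number, and majority-rule label refinement.

relabel_contiguous <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

snn_graph <- function(x, k) {
  n <- nrow(x)
  nn <- FNN::get.knn(x, k = min(k, n - 1))$nn.index
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = ncol(nn)),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  diag(A) <- 1                      # neighbor sets include the point itself
  S <- Matrix::tcrossprod(A)        # shared-neighbor counts
  S <- methods::as(S, "TsparseMatrix")
  keep <- S@i < S@j
  i <- S@i[keep] + 1L; j <- S@j[keep] + 1L
  shared <- S@x[keep]
  w <- shared / (2 * (k + 1) - shared)
  sel <- w > 0
  igraph::graph_from_data_frame(
    data.frame(from = i[sel], to = j[sel], weight = w[sel]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
}

knn_graph <- function(x, k) {
  n <- nrow(x)
  nn <- FNN::get.knn(x, k = min(k, n - 1))$nn.index
  el <- cbind(rep(seq_len(n), each = ncol(nn)), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)
}

#' Cluster locations on spatial PCs
#'
#' Detects spatial domains by community detection on a neighbor graph built
#' from Euclidean distances in PC space: Walktrap on a shared-nearest-neighbor
#' (SNN) graph, or Louvain on a k-nearest-neighbor (KNN) graph. The community
#' count is steered to `target_clusters` by cutting the Walktrap dendrogram,
#' or by bisection on the Louvain resolution parameter (at most 50 attempts).
#'
#' @param Z d x n matrix of spatial PCs (factors in rows).
#' @param method `"walktrap_snn"` or `"louvain_knn"`.
#' @param target_clusters desired number of domains (>= 2).
#' @param knn_k neighborhood size for the graphs (default 10).
#' @param seed integer seed (Louvain is randomized).
#'
#' @return An object of class `DomainLabeling`: list with `labels`
#'   (integer 1..C per location), `C`, `method`, `refined = FALSE`.
#' @export
cluster_pcs <- function(Z, method = c("walktrap_snn", "louvain_knn"),
                        target_clusters, knn_k = 10, seed = 1L) {
  method <- match.arg(method)
  x <- t(as.matrix(Z))
  n <- nrow(x)
  if (target_clusters < 2 || target_clusters > n)
    stop("target_clusters must be in [2, n]")
  if (method == "walktrap_snn") {
    g <- snn_graph(x, knn_k)
    set.seed(seed)
    wt <- igraph::cluster_walktrap(g)
    labels <- suppressWarnings(igraph::cut_at(wt, no = target_clusters))
    if (length(unique(labels)) != target_clusters) {
      floor_c <- length(unique(suppressWarnings(igraph::cut_at(wt, no = 1))))
      stop(sprintf("cannot cut dendrogram into %d clusters (achievable: %d..%d)",
                   target_clusters, floor_c, n))
    }
  } else {
    g <- knn_graph(x, knn_k)
    lo <- 0.01; hi <- 5
    labels <- NULL
    for (attempt in seq_len(50)) {
      res <- (lo + hi) / 2
      set.seed(seed)
      cl <- igraph::cluster_louvain(g, resolution = res)
      memb <- igraph::membership(cl)
      nc <- length(unique(memb))
      if (nc == target_clusters) { labels <- memb; break }
      if (nc < target_clusters) lo <- res else hi <- res
    }
    if (is.null(labels))
      stop(sprintf("louvain could not reach %d clusters within 50 resolution steps (last count %d)",
                   target_clusters, nc))
  }
  labels <- relabel_contiguous(as.integer(labels))
  structure(list(labels = labels, C = length(unique(labels)),
                 method = method, refined = FALSE),
            class = "DomainLabeling")
}

#' @export
print.DomainLabeling <- function(x, ...) {
  cat(sprintf("DomainLabeling: %d locations, %d domains (%s%s)\n",
              length(x$labels), x$C, x$method,
              if (x$refined) ", refined" else ""))
  invisible(x)
}

#' Choose the number of spatial domains
#'
#' Clusters the locations for each candidate count and returns the candidate
#' with the highest average silhouette width on PC-space Euclidean distances.
#' Candidates producing singleton clusters (silhouette undefined) are
#' skipped; ties go to the smaller count.
#'
#' @param Z d x n matrix of spatial PCs.
#' @param candidates integer vector of candidate cluster counts (within
#'   [2, n-1]).
#' @param coords optional `SpatialCoordinates`, carried for interface
#'   completeness (the silhouette is computed in PC space).
#' @param method,knn_k,seed passed to [cluster_pcs()].
#'
#' @return The selected cluster count.
#' @export
choose_cluster_number <- function(Z, candidates, coords = NULL,
                                  method = "walktrap_snn", knn_k = 10,
                                  seed = 1L) {
  x <- t(as.matrix(Z))
  n <- nrow(x)
  candidates <- sort(unique(as.integer(candidates)))
  if (any(candidates < 2 | candidates > n - 1))
    stop("candidates must lie in [2, n-1]")
  dd <- stats::dist(x)
  best <- NA_integer_; best_sil <- -Inf
  for (cc in candidates) {
    lab <- tryCatch(cluster_pcs(Z, method, cc, knn_k, seed)$labels,
                    error = function(e) NULL)
    if (is.null(lab) || min(table(lab)) < 2) next
    sil <- cluster::silhouette(lab, dd)
    avg <- mean(sil[, "sil_width"])
    if (avg > best_sil + 1e-12) { best <- cc; best_sil <- avg }
  }
  if (is.na(best)) stop("no candidate produced a valid silhouette")
  best
}

#' Spatially refine domain labels
#'
#' Single-pass majority smoothing of domain labels: for each location, the
#' labels of its `neighbor_count` nearest locations (Euclidean distance on the
#' scaled coordinates) plus its own are tallied against the pre-pass labeling;
#' if a strict-majority label exists and differs from the location's label,
#' the location is relabeled. Four neighbors mirror the ST square lattice, six
#' the Visium hexagonal lattice.
#'
#' @param labeling a `DomainLabeling`.
#' @param coords `SpatialCoordinates` of the locations.
#' @param neighbor_count number of surrounding locations to consult.
#' @return A new `DomainLabeling` with `refined = TRUE`.
#' @export
refine_labels <- function(labeling, coords, neighbor_count = 6) {
  stopifnot(inherits(labeling, "DomainLabeling"),
            inherits(coords, "SpatialCoordinates"))
  if (neighbor_count < 1) stop("neighbor_count must be >= 1")
  old <- labeling$labels
  n <- length(old)
  nn <- FNN::get.knn(coords$coords, k = min(neighbor_count, n - 1))$nn.index
  new <- old
  half <- (ncol(nn) + 1) / 2
  for (i in seq_len(n)) {
    tab <- table(c(old[i], old[nn[i, ]]))
    top <- tab[which.max(tab)]
    if (top > half && names(top) != as.character(old[i]))
      new[i] <- as.integer(names(top))
  }
  structure(list(labels = new, C = labeling$C, method = labeling$method,
                 refined = TRUE),
            class = "DomainLabeling")
}
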