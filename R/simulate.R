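# Synthetic layered-tissue generator: band/stripe geometries on a pixel
# lattice, per-layer multinomial cell-type compositions, gamma-Poisson
# (splat-style) counts with group-specific DE factors, square-grid
# subspot/spot aggregation, and the cell-split neighbor-sharing variant.

layer_dominance_orders <- list(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 1L),
                               c(3L, 4L, 1L, 2L), c(4L, 1L, 2L, 3L))

scenario_compositions <- list(
  S1 = c(0.70, 0.10, 0.10, 0.10),
  S2 = c(0.45, 0.45, 0.05, 0.05),
  S3 = c(0.60, 0.30, 0.05, 0.05),
  S4 = c(0.35, 0.30, 0.30, 0.05),
  stripe1 = c(0.60, 0.40, 0.00, 0.00),
  stripe2 = c(0.60, 0.30, 0.05, 0.05),
  stripe3 = c(0.60, 0.20, 0.20, 0.00))

#' Layered synthetic tissue geometry
#'
#' Samples single-cell positions on a pixel lattice and assigns each cell a
#' spatial-domain label: `bands4` divides the lattice into four parallel
#' equal-area bands (a cortical-layer caricature, labels 1-4); `stripes6`
#' divides it into six equal-width vertical stripes with the three odd stripes
#' forming domain 1 and the three even stripes domain 2 (a spatially
#' non-contiguous pattern).
#'
#' @param n_cells number of cells (at most the lattice size).
#' @param lattice integer `c(width, height)` of the pixel lattice.
#' @param layout `"bands4"` or `"stripes6"`.
#' @param seed integer seed.
#'
#' @return An object of class `SyntheticTissue` with `cell_coords` (n x 2),
#'   `layer_labels`, `lattice`, `layout`, `seed`; cell types and counts are
#'   added by [assign_cell_types()] and [simulate_counts_splatlike()].
#' @export
make_layered_tissue <- function(n_cells, lattice = c(100L, 100L),
                                layout = c("bands4", "stripes6"),
                                seed = 1L) {
  layout <- match.arg(layout)
  w <- lattice[1]; h <- lattice[2]
  if (n_cells > w * h) stop("n_cells exceeds the lattice size")
  set.seed(seed)
  idx <- sample.int(w * h, n_cells)
  x <- ((idx - 1L) %% w) + 1L
  y <- ((idx - 1L) %/% w) + 1L
  labels <- if (layout == "bands4") {
    pmin(ceiling(y / (h / 4)), 4L)
  } else {
    stripe <- pmin(ceiling(x / (w / 6)), 6L)
    ifelse(stripe %% 2 == 1, 1L, 2L)
  }
  coords <- cbind(x = x, y = y)
  rownames(coords) <- paste0("cell", seq_len(n_cells))
  structure(list(cell_coords = coords, layer_labels = as.integer(labels),
                 cell_types = NULL, counts = NULL,
                 lattice = c(w, h), layout = layout, seed = seed),
            class = "SyntheticTissue")
}

#' @export
print.SyntheticTissue <- function(x, ...) {
  cat(sprintf("SyntheticTissue: %d cells on a %d x %d lattice (%s, %d domains)\n",
              nrow(x$cell_coords), x$lattice[1], x$lattice[2], x$layout,
              length(unique(x$layer_labels))))
  if (!is.null(x$counts))
    cat(sprintf("  counts: %d genes\n", nrow(x$counts)))
  if (!is.null(x$spot_counts))
    cat(sprintf("  aggregated: %d subspots, %d spots\n",
                ncol(x$subspot_counts), ncol(x$spot_counts)))
  invisible(x)
}

#' Assign cell types by layer composition
#'
#' Draws each cell's type (1-4) independently from a multinomial distribution
#' whose composition depends on the cell's spatial domain. The dominance order
#' of the four types rotates across layers (1,2,3,4 / 2,3,4,1 / 3,4,1,2 /
#' 4,1,2,3), and the proportions attached to the ranked types are set by the
#' scenario: `S1` = 70/10/10/10, `S2` = 45/45/5/5, `S3` = 60/30/5/5,
#' `S4` = 35/30/30/5; the stripe scenarios (two domains) use
#' `stripe1` = 60/40, `stripe2` = 60/30/5/5, `stripe3` = 60/20/20.
#'
#' @param tissue a [make_layered_tissue()] result.
#' @param scenario one of `"S1".."S4"`, `"stripe1".."stripe3"`.
#' @param seed integer seed.
#' @return The tissue with `cell_types` filled in.
#' @export
assign_cell_types <- function(tissue, scenario, seed = 1L) {
  stopifnot(inherits(tissue, "SyntheticTissue"))
  if (!scenario %in% names(scenario_compositions))
    stop("unknown scenario: ", scenario)
  props <- scenario_compositions[[scenario]]
  set.seed(seed)
  types <- integer(nrow(tissue$cell_coords))
  for (lay in sort(unique(tissue$layer_labels))) {
    ord <- layer_dominance_orders[[lay]]
    idx <- which(tissue$layer_labels == lay)
    types[idx] <- sample(ord, length(idx), replace = TRUE, prob = props)
  }
  tissue$cell_types <- types
  tissue$scenario <- scenario
  tissue
}

#' Composition table for a scenario
#'
#' The expected cell-type proportions (columns: types 1-4) per spatial domain
#' (rows) under a scenario, i.e. the multinomial parameters used by
#' [assign_cell_types()].
#'
#' @param scenario scenario name.
#' @param n_layers number of spatial domains (4 for bands, 2 for stripes).
#' @return A `n_layers` x 4 matrix of proportions.
#' @export
scenario_composition <- function(scenario, n_layers = 4) {
  props <- scenario_compositions[[scenario]]
  if (is.null(props)) stop("unknown scenario: ", scenario)
  out <- matrix(0, n_layers, 4,
                dimnames = list(paste0("domain", seq_len(n_layers)),
                                paste0("type", 1:4)))
  for (lay in seq_len(n_layers))
    out[lay, layer_dominance_orders[[lay]]] <- props
  out
}

#' Gamma-Poisson (splat-style) count simulation
#'
#' Simulates a gene x cell count matrix from a hierarchical gamma-Poisson
#' model with group-specific differential expression: gene base means are
#' gamma distributed; within each group a `de_prob` fraction of genes receives
#' a multiplicative log-normal DE factor (up- or down-regulation with equal
#' probability); per-cell library sizes are log-normal; counts are Poisson
#' with rate `library_size * group-specific expression proportion`.
#'
#' Default distribution constants: gene-mean gamma shape 0.6 / rate 0.3, DE
#' factor log-normal location 0.1 / scale 0.4, library-size log-normal
#' location 11 / scale 0.2.
#'
#' @param n_genes,n_cells dimensions.
#' @param n_groups number of cell groups.
#' @param de_prob probability a gene is differentially expressed in a group.
#' @param group_prob group probabilities (must sum to 1); ignored when
#'   `groups` is supplied.
#' @param seed integer seed.
#' @param groups optional explicit group assignment per cell.
#' @param params optional list overriding the distribution constants
#'   (`mean_shape`, `mean_rate`, `de_facloc`, `de_facscale`, `lib_loc`,
#'   `lib_scale`), e.g. values estimated from an empirical reference.
#'
#' @return List with `counts` (gene x cell integer matrix), `groups`,
#'   `de_factors` (gene x group multiplicative factors), `base_means`.
#' @export
simulate_counts_splatlike <- function(n_genes, n_cells, n_groups = 4,
                                      de_prob = 0.5,
                                      group_prob = rep(1 / n_groups, n_groups),
                                      seed = 1L, groups = NULL,
                                      params = list()) {
  p <- utils::modifyList(list(mean_shape = 0.6, mean_rate = 0.3,
                              de_facloc = 0.1, de_facscale = 0.4,
                              lib_loc = 11, lib_scale = 0.2), params)
  if (abs(sum(group_prob) - 1) > 1e-8) stop("group_prob must sum to 1")
  set.seed(seed)
  base <- stats::rgamma(n_genes, shape = p$mean_shape, rate = p$mean_rate)
  fac <- matrix(1, n_genes, n_groups)
  for (g in seq_len(n_groups)) {
    de <- stats::runif(n_genes) < de_prob
    f <- stats::rlnorm(sum(de), p$de_facloc, p$de_facscale)
    down <- stats::runif(sum(de)) < 0.5
    f[down] <- 1 / f[down]
    fac[de, g] <- f
  }
  if (is.null(groups)) {
    groups <- sample.int(n_groups, n_cells, replace = TRUE, prob = group_prob)
  } else {
    groups <- as.integer(groups)
    if (length(groups) != n_cells) stop("groups must have length n_cells")
  }
  lib <- stats::rlnorm(n_cells, p$lib_loc, p$lib_scale)
  gm <- base * fac                               # gene x group expected means
  prop <- sweep(gm, 2, colSums(gm), "/")         # expression proportions
  lambda <- prop[, groups, drop = FALSE] * rep(lib, each = n_genes)
  counts <- matrix(stats::rpois(n_genes * n_cells, lambda), n_genes, n_cells,
                   dimnames = list(paste0("gene", seq_len(n_genes)),
                                   paste0("cell", seq_len(n_cells))))
  list(counts = counts, groups = groups, de_factors = fac, base_means = base)
}

#' Attach simulated counts to a tissue
#'
#' Convenience wrapper: simulates splat-style counts with the tissue's
#' cell-type assignment as the group labels and stores the matrix on the
#' tissue.
#'
#' @param tissue a tissue with cell types ([assign_cell_types()]).
#' @param n_genes number of genes.
#' @param de_prob DE probability per gene and group (default 0.5).
#' @param seed integer seed.
#' @param params see [simulate_counts_splatlike()].
#' @return The tissue with `counts` filled in.
#' @export
simulate_tissue_counts <- function(tissue, n_genes, de_prob = 0.5, seed = 1L,
                                   params = list()) {
  stopifnot(inherits(tissue, "SyntheticTissue"))
  if (is.null(tissue$cell_types)) stop("assign cell types first")
  sim <- simulate_counts_splatlike(n_genes, nrow(tissue$cell_coords),
                                   n_groups = 4, de_prob = de_prob,
                                   seed = seed, groups = tissue$cell_types)
  colnames(sim$counts) <- rownames(tissue$cell_coords)
  tissue$counts <- sim$counts
  tissue
}

majority_label <- function(labels) {
  tab <- table(labels)
  as.integer(names(tab)[which.max(tab)])
}

#' Aggregate cells into square-grid subspots and spots
#'
#' Tiles the tissue with a square grid of edge `grid_edge`; each grid cell is
#' a subspot whose counts are the sum over its cells and whose truth label is
#' the majority domain label of its cells. Subspots are then merged 3 x 3 into
#' spots, with the spot coordinate taken from the center subspot and the spot
#' label from the majority over the spot's cells. Spots containing no cells
#' are dropped; empty subspots inside retained spots carry zero counts.
#'
#' @param tissue a tissue with counts.
#' @param grid_edge side length of a subspot square (lattice units).
#' @return The tissue with `subspot_counts`, `subspot_coords`,
#'   `subspot_labels`, `subspot_map` (cell -> subspot), `spot_counts`,
#'   `spot_coords`, `spot_labels`, `spot_map` (subspot -> spot) added.
#' @export
aggregate_to_spots <- function(tissue, grid_edge) {
  stopifnot(inherits(tissue, "SyntheticTissue"))
  if (is.null(tissue$counts)) stop("simulate counts first")
  if (grid_edge <= 0) stop("grid_edge must be positive")
  xy <- tissue$cell_coords
  if (grid_edge > max(tissue$lattice)) stop("grid larger than the tissue")
  sx <- floor((xy[, 1] - 1) / grid_edge)           # 0-based subspot column
  sy <- floor((xy[, 2] - 1) / grid_edge)
  bx <- sx %/% 3L; by <- sy %/% 3L                 # spot block indices
  spot_key_cell <- paste(bx, by, sep = "_")
  keep_spots <- unique(spot_key_cell)              # spots containing cells
  # enumerate all 9 subspots of each retained spot
  sub_tab <- do.call(rbind, lapply(keep_spots, function(k) {
    b <- as.integer(strsplit(k, "_")[[1]])
    expand.grid(sx = 3 * b[1] + 0:2, sy = 3 * b[2] + 0:2,
                KEEP.OUT.ATTRS = FALSE)
  }))
  sub_key <- paste(sub_tab$sx, sub_tab$sy, sep = "_")
  sub_key_cell <- paste(sx, sy, sep = "_")
  n_sub <- nrow(sub_tab)
  g <- nrow(tissue$counts)
  sub_counts <- matrix(0L, g, n_sub,
                       dimnames = list(rownames(tissue$counts),
                                       paste0("subspot", seq_len(n_sub))))
  sub_labels <- rep(NA_integer_, n_sub)
  cell_sub <- match(sub_key_cell, sub_key)
  for (jj in unique(cell_sub)) {
    members <- which(cell_sub == jj)
    sub_counts[, jj] <- rowSums(tissue$counts[, members, drop = FALSE])
    sub_labels[jj] <- majority_label(tissue$layer_labels[members])
  }
  sub_coords <- cbind(x = (sub_tab$sx + 0.5) * grid_edge,
                      y = (sub_tab$sy + 0.5) * grid_edge)
  rownames(sub_coords) <- colnames(sub_counts)
  # spots: 3x3 merge; coordinate from the center subspot
  sub_bx <- sub_tab$sx %/% 3L; sub_by <- sub_tab$sy %/% 3L
  spot_key_sub <- paste(sub_bx, sub_by, sep = "_")
  spot_ids <- unique(spot_key_sub)
  n_spot <- length(spot_ids)
  spot_counts <- matrix(0L, g, n_spot,
                        dimnames = list(rownames(tissue$counts),
                                        paste0("spot", seq_len(n_spot))))
  spot_coords <- matrix(0, n_spot, 2, dimnames = list(NULL, c("x", "y")))
  spot_labels <- integer(n_spot)
  spot_map <- match(spot_key_sub, spot_ids)
  for (jj in seq_len(n_spot)) {
    subs <- which(spot_map == jj)
    spot_counts[, jj] <- rowSums(sub_counts[, subs, drop = FALSE])
    b <- as.integer(strsplit(spot_ids[jj], "_")[[1]])
    spot_coords[jj, ] <- c((3 * b[1] + 1.5) * grid_edge,
                           (3 * b[2] + 1.5) * grid_edge)
    cells <- which(paste(bx, by, sep = "_") == spot_ids[jj])
    spot_labels[jj] <- majority_label(tissue$layer_labels[cells])
  }
  rownames(spot_coords) <- colnames(spot_counts)
  tissue$subspot_counts <- sub_counts
  tissue$subspot_coords <- sub_coords
  tissue$subspot_labels <- sub_labels
  tissue$subspot_map <- cell_sub
  tissue$spot_counts <- spot_counts
  tissue$spot_coords <- spot_coords
  tissue$spot_labels <- spot_labels
  tissue$spot_map <- spot_map
  tissue$grid_edge <- grid_edge
  tissue
}

#' Split cells and share counts with neighbors
#'
#' Emulates the count sharing between neighboring locations seen in
#' non-single-cell platforms: `n_split` randomly chosen cells are removed and
#' each one's counts are divided into four parts with uniform (Dirichlet)
#' random weights summing to one, each part being added to one of the cell's
#' four nearest surviving cells. Integer counts are preserved by multinomial
#' (stochastic-rounding) allocation, so the total count sum is conserved
#' exactly.
#'
#' @param tissue a tissue with counts.
#' @param n_split number of cells to split (less than the cell count).
#' @param seed integer seed.
#' @return The tissue with `n_cells - n_split` pseudo-cells.
#' @export
cell_split <- function(tissue, n_split, seed = 1L) {
  stopifnot(inherits(tissue, "SyntheticTissue"))
  if (is.null(tissue$counts)) stop("simulate counts first")
  n <- nrow(tissue$cell_coords)
  if (n_split >= n) stop("n_split must be smaller than the cell count")
  set.seed(seed)
  split_idx <- sample.int(n, n_split)
  surv <- setdiff(seq_len(n), split_idx)
  counts <- tissue$counts
  nn <- FNN::get.knnx(tissue$cell_coords[surv, , drop = FALSE],
                      tissue$cell_coords[split_idx, , drop = FALSE], k = 4)
  for (ii in seq_along(split_idx)) {
    tgt <- surv[nn$nn.index[ii, ]]
    w <- stats::rexp(4); w <- w / sum(w)           # uniform on the simplex
    c_vec <- counts[, split_idx[ii]]
    rem <- c_vec
    wr <- w
    for (t in 1:3) {
      a <- stats::rbinom(length(rem), rem, wr[1] / sum(wr))
      counts[, tgt[t]] <- counts[, tgt[t]] + a
      rem <- rem - a
      wr <- wr[-1]
    }
    counts[, tgt[4]] <- counts[, tgt[4]] + rem
  }
  tissue$counts <- counts[, surv, drop = FALSE]
  tissue$cell_coords <- tissue$cell_coords[surv, , drop = FALSE]
  tissue$layer_labels <- tissue$layer_labels[surv]
  if (!is.null(tissue$cell_types)) tissue$cell_types <- tissue$cell_types[surv]
  tissue$n_split <- n_split
  tissue
}
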