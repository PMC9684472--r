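#' One-stop spatially aware PCA
#'
#' Convenience wrapper running the full pipeline on a count (or
#' pre-normalized) matrix and raw coordinates: detection filtering,
#' log-normalization and gene standardization, optional gene selection,
#' coordinate scaling, expression-derived bandwidth selection, Gaussian kernel
#' construction with low-rank truncation, model fitting and posterior spatial
#' PCs.
#'
#' @param expr an [expression_matrix()] (counts or normalized).
#' @param coords a [spatial_coordinates()] object aligned with the expression
#'   columns.
#' @param d number of spatial PCs (default 20).
#' @param min_locations_per_gene,min_genes_per_location detection filter
#'   thresholds (counts input only; default 20/20).
#' @param gene_mode,gene_k,gene_list optional gene selection (see
#'   [select_genes()]); `gene_mode = NULL` keeps all genes.
#' @param bandwidth `"auto"` (see [select_bandwidth()]) or a positive number.
#' @param sparse_cutoff kernel sparsity cutoff (default 1e-20).
#' @param variance_threshold low-rank variance fraction (default 0.9).
#' @param covariates optional location x q-1 matrix of extra covariates.
#'
#' @return A `SpatialPCAFit` (see [spatial_pca_fit()]); the filtered
#'   standardized expression is attached as `$expr`.
#' @export
spatial_pca <- function(expr, coords, d = 20,
                        min_locations_per_gene = 20,
                        min_genes_per_location = 20,
                        gene_mode = NULL, gene_k = NULL, gene_list = NULL,
                        bandwidth = "auto", sparse_cutoff = 1e-20,
                        variance_threshold = 0.9, covariates = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(coords, "SpatialCoordinates"))
  if (ncol(expr$values) != nrow(coords$coords))
    stop("expression columns and coordinate rows must match")
  if (expr$state == "counts")
    expr <- filter_matrix(expr, min_locations_per_gene, min_genes_per_location)
  if (!is.null(gene_mode))
    expr <- select_genes(expr, gene_mode, k = gene_k, gene_list = gene_list)
  keep <- match(expr$location_ids, rownames(coords$coords))
  std <- normalize_and_standardize(expr)
  keep <- keep[match(std$location_ids, expr$location_ids)]
  sc <- scale_coordinates(spatial_coordinates(
    coords$coords[keep, , drop = FALSE]))
  gamma <- if (identical(bandwidth, "auto"))
    select_bandwidth(std) else as.numeric(bandwidth)
  kern <- build_kernel(sc, gamma, sparse_cutoff = sparse_cutoff)
  kern <- lowrank_eigen(kern, variance_threshold)
  cov <- covariate_table(ncol(std$values),
                         covariates = if (!is.null(covariates))
                           covariates[keep, , drop = FALSE],
                         location_ids = std$location_ids)
  fit <- spatial_pca_fit(std, kern, d = d, covariates = cov)
  fit$expr <- std
  fit
}
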