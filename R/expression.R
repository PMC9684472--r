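#' Expression matrix container
#'
#' Lightweight container for a gene x location expression matrix together with
#' identifiers and a normalization-state flag. All model functions in this
#' package consume and produce `ExpressionMatrix` objects so that the state of
#' the values (raw counts, library-size normalized, or gene-standardized) is
#' always explicit.
#'
#' @param values numeric gene x location matrix.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   rownames of `values`).
#' @param location_ids character vector of unique location identifiers
#'   (defaults to colnames of `values`).
#' @param state one of `"counts"`, `"normalized"`, `"standardized"`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `location_ids`, `state`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              location_ids = colnames(values),
                              state = c("counts", "normalized", "standardized")) {
  state <- match.arg(state)
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  if (is.null(location_ids)) location_ids <- paste0("loc", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  location_ids <- as.character(location_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length must equal nrow(values)")
  if (length(location_ids) != ncol(values))
    stop("location_ids length must equal ncol(values)")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids are not allowed")
  if (anyDuplicated(location_ids)) stop("duplicate location_ids are not allowed")
  if (anyNA(values) || any(!is.finite(values)))
    stop("missing or non-finite expression values are rejected, not imputed")
  if (state == "counts" && (any(values < 0) || any(values != round(values))))
    stop("state = 'counts' requires non-negative integer values")
  dimnames(values) <- list(gene_ids, location_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 location_ids = location_ids, state = state),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d locations (state: %s)\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Covariate table with intercept
#'
#' Builds the location-level covariate matrix used by the factor model. The
#' first column is always an intercept column of ones; the regression
#' coefficients on these covariates are integrated out of the marginal
#' likelihood, which for an intercept-only table amounts to per-gene centering
#' over locations.
#'
#' @param n number of locations.
#' @param covariates optional location x (q-1) numeric matrix of extra
#'   covariates (no intercept; one is added).
#' @param location_ids optional location identifiers.
#'
#' @return An object of class `CovariateTable` with elements `values`
#'   (location x q, first column ones) and `q`.
#' @export
covariate_table <- function(n, covariates = NULL, location_ids = NULL) {
  X <- matrix(1, nrow = n, ncol = 1)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per location")
    if (anyNA(covariates)) stop("missing covariate values are rejected")
    X <- cbind(X, covariates)
  }
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  colnames(X) <- c("(Intercept)",
                   if (ncol(X) > 1) paste0("x", seq_len(ncol(X) - 1L)))
  if (!is.null(location_ids)) rownames(X) <- location_ids
  structure(list(values = X, q = ncol(X)), class = "CovariateTable")
}

#' Filter genes and locations by detection
#'
#' Removes lowly detected genes and sparsely covered locations from a count
#' matrix: genes are required to have non-zero counts in at least
#' `min_locations_per_gene` locations, then locations are required to have
#' non-zero counts for at least `min_genes_per_location` of the surviving
#' genes. The defaults (20, 20) are the detection filter commonly applied to
#' spot-level spatial transcriptomics.
#'
#' @param expr an [expression_matrix()] in `counts` state.
#' @param min_locations_per_gene minimum locations with non-zero counts per
#'   retained gene.
#' @param min_genes_per_location minimum genes with non-zero counts per
#'   retained location.
#'
#' @return The filtered `ExpressionMatrix` (still `counts`).
#' @export
filter_matrix <- function(expr, min_locations_per_gene = 20,
                          min_genes_per_location = 20) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$state != "counts") stop("filter_matrix expects a counts matrix")
  v <- expr$values
  keep_g <- rowSums(v > 0) >= min_locations_per_gene
  if (!any(keep_g))
    stop(sprintf("no genes detected in >= %d locations", min_locations_per_gene))
  v <- v[keep_g, , drop = FALSE]
  keep_l <- colSums(v > 0) >= min_genes_per_location
  if (!any(keep_l))
    stop(sprintf("no locations with >= %d detected genes", min_genes_per_location))
  v <- v[, keep_l, drop = FALSE]
  expression_matrix(v, state = "counts")
}

#' Log-normalize and gene-standardize expression
#'
#' Counts are library-size normalized per location (totals scaled to
#' `scale_constant`, then `log1p`); pre-normalized input skips that step. Every
#' gene is then centered and scaled to unit sample standard deviation, the form
#' the factor model expects. Genes with zero variance are dropped with a
#' warning, as are locations with zero total counts.
#'
#' @param expr an [expression_matrix()] in `counts` or `normalized` state.
#' @param scale_constant per-location total after library-size scaling
#'   (default 10000).
#'
#' @return An `ExpressionMatrix` in `standardized` state: every gene row has
#'   mean 0 and sample SD 1.
#' @export
normalize_and_standardize <- function(expr, scale_constant = 1e4) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$state == "standardized") return(expr)
  v <- expr$values
  if (expr$state == "counts") {
    tot <- colSums(v)
    if (any(tot == 0)) {
      warning(sprintf("dropping %d location(s) with zero total counts", sum(tot == 0)))
      v <- v[, tot > 0, drop = FALSE]
      tot <- tot[tot > 0]
      if (ncol(v) < 2) stop("fewer than 2 locations with counts; cannot standardize")
    }
    v <- log1p(sweep(v, 2, tot / scale_constant, "/"))
  }
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  if (any(sdv <= 0)) {
    warning(sprintf("dropping %d zero-variance gene(s)", sum(sdv <= 0)))
    keep <- sdv > 0
    v <- v[keep, , drop = FALSE]
    mu <- mu[keep]; sdv <- sdv[keep]
    if (nrow(v) == 0) stop("all genes have zero variance")
  }
  v <- (v - mu) / sdv
  expression_matrix(v, state = "standardized")
}

#' Select input genes
#'
#' Restricts the matrix to a named gene list (e.g. spatially variable genes
#' selected by an external tool) or, as a convenience, to the `k` most highly
#' variable genes of the normalized expression.
#'
#' @param expr an `ExpressionMatrix`.
#' @param mode `"list"` (keep `gene_list`, in the given order) or `"hvg"`
#'   (keep the `k` genes with largest variance of normalized expression).
#' @param k number of genes for `mode = "hvg"`.
#' @param gene_list character vector of gene ids for `mode = "list"`.
#'
#' @return The restricted `ExpressionMatrix` (state unchanged).
#' @export
select_genes <- function(expr, mode = c("list", "hvg"), k = NULL,
                         gene_list = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  mode <- match.arg(mode)
  if (mode == "list") {
    if (is.null(gene_list)) stop("mode = 'list' requires gene_list")
    missing <- setdiff(gene_list, expr$gene_ids)
    if (length(missing))
      stop("requested genes absent: ", paste(missing, collapse = ", "))
    v <- expr$values[gene_list, , drop = FALSE]
  } else {
    if (is.null(k)) stop("mode = 'hvg' requires k")
    if (k > nrow(expr$values)) stop("k exceeds the number of genes")
    w <- expr$values
    if (expr$state == "counts") {
      tot <- pmax(colSums(w), 1)
      w <- log1p(sweep(w, 2, tot / 1e4, "/"))
    }
    vars <- apply(w, 1, stats::var)
    keep <- order(vars, decreasing = TRUE)[seq_len(k)]
    v <- expr$values[sort(keep), , drop = FALSE]
  }
  expression_matrix(v, state = expr$state)
}
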