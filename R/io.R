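#' Read expression from Matrix Market files
#'
#' Reads a sparse gene x location count matrix in Matrix Market triplet format
#' with companion one-column gene and barcode (location) text files, the layout
#' produced by most spatial transcriptomics pipelines.
#'
#' @param mtx path to the `.mtx` file (genes in rows, locations in columns).
#' @param genes path to the gene id file (one id per line).
#' @param barcodes path to the location/barcode id file (one id per line).
#' @param state state flag for the values (default `"counts"`).
#'
#' @return An [expression_matrix()].
#' @export
read_expression_mtx <- function(mtx, genes, barcodes, state = "counts") {
  m <- as.matrix(Matrix::readMM(mtx))
  gid <- readLines(genes)
  bid <- readLines(barcodes)
  expression_matrix(m, gene_ids = gid, location_ids = bid, state = state)
}

#' Write expression to Matrix Market files
#'
#' @param expr an `ExpressionMatrix`.
#' @param mtx,genes,barcodes output paths (see [read_expression_mtx()]).
#' @return Invisibly, the `mtx` path.
#' @export
write_expression_mtx <- function(expr, mtx, genes, barcodes) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  Matrix::writeMM(Matrix::Matrix(expr$values, sparse = TRUE), mtx)
  writeLines(expr$gene_ids, genes)
  writeLines(expr$location_ids, barcodes)
  invisible(mtx)
}

#' Read expression from a dense delimited file
#'
#' Expects a header row of location ids and a first column of gene ids.
#' The delimiter is inferred from the file extension (`.csv` = comma,
#' otherwise tab).
#'
#' @param path input file.
#' @param state state flag for the values.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, state = "counts") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                         check.names = FALSE, stringsAsFactors = FALSE)
  expression_matrix(as.matrix(d), state = state)
}

#' Write expression to a dense delimited file
#'
#' @param expr an `ExpressionMatrix`.
#' @param path output file; `.csv` writes comma-separated, otherwise tabs.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(expr, path) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- data.frame(gene = expr$gene_ids, expr$values, check.names = FALSE)
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read spatial coordinates
#'
#' Reads a coordinate table with columns `id, x, y` (and optionally `z`). The
#' file order defines the canonical location order used throughout the
#' package.
#'
#' @param path delimited file (`.csv` = comma, otherwise tab) with a header.
#' @return A [spatial_coordinates()] object (unscaled).
#' @export
read_coordinates <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  axes <- intersect(c("x", "y", "z"), colnames(d))
  if (length(axes) < 2) stop("coordinate file must contain x and y columns")
  m <- as.matrix(d[, axes, drop = FALSE])
  rownames(m) <- as.character(d$id)
  spatial_coordinates(m)
}

#' Write spatial coordinates
#'
#' @param coords a `SpatialCoordinates` object (written on its current scale).
#' @param path output file; `.csv` writes comma-separated, otherwise tabs.
#' @return Invisibly, `path`.
#' @export
write_coordinates <- function(coords, path) {
  stopifnot(inherits(coords, "SpatialCoordinates"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- data.frame(id = rownames(coords$coords), coords$coords,
                  check.names = FALSE)
  colnames(d) <- c("id", c("x", "y", "z")[seq_len(ncol(coords$coords))])
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
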