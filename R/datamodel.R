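#' @import methods
#' @importFrom Matrix colSums rowSums rowMeans colMeans t
NULL

#' CountMatrix: sparse genes-by-cells UMI counts
#'
#' Extends `Matrix::dgCMatrix` (10x convention: features are rows) with a
#' per-cell `sample_labels` slot. Counts must be non-negative integers and
#' gene symbols / barcodes (the dimnames) unique within their axis.
#'
#' @slot sample_labels Character, one per cell (may be length 0 when unused).
#' @exportClass CountMatrix
setClass("CountMatrix", contains = "dgCMatrix",
         representation(sample_labels = "character"))

setValidity("CountMatrix", function(object) {
  msgs <- character()
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msgs <- c(msgs, "gene symbols (rownames) and barcodes (colnames) required")
  else {
    if (anyDuplicated(rownames(object)))
      msgs <- c(msgs, "duplicate gene symbols")
    if (anyDuplicated(colnames(object)))
      msgs <- c(msgs, "duplicate barcodes")
  }
  if (length(object@x)) {
    if (any(object@x < 0)) msgs <- c(msgs, "negative counts")
    if (any(object@x != round(object@x))) msgs <- c(msgs, "non-integer counts")
  }
  if (length(object@sample_labels) &&
      length(object@sample_labels) != ncol(object))
    msgs <- c(msgs, "sample_labels must have one entry per cell")
  if (length(msgs)) msgs else TRUE
})

#' NormalizedMatrix: size-factor-normalized expression
#'
#' Sparse real genes-by-cells matrix with `value(g,c) = count(g,c) /
#' size_factor(c)` exactly; carries the size factors and the provenance of
#' the source `CountMatrix`.
#'
#' @slot size_factors Numeric, one positive factor per cell.
#' @slot provenance List describing the source matrix.
#' @exportClass NormalizedMatrix
setClass("NormalizedMatrix", contains = "dgCMatrix",
         representation(size_factors = "numeric", provenance = "list"))

#' Construct a CountMatrix
#'
#' @param counts Matrix or sparse Matrix of non-negative integer UMI counts,
#'   genes in rows, cells in columns.
#' @param gene_symbols Unique gene symbols, one per row (default: rownames).
#' @param barcodes Unique cell barcodes, one per column (default: colnames).
#' @param sample_labels Optional per-cell sample tag (recycled if length 1).
#' @return A `CountMatrix`.
#' @export
count_matrix <- function(counts, gene_symbols = rownames(counts),
                         barcodes = colnames(counts), sample_labels = NULL) {
  m <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_symbols) || is.null(barcodes))
    stop("gene_symbols and barcodes are required (directly or as dimnames)")
  if (length(gene_symbols) != nrow(m)) stop("length(gene_symbols) != nrow(counts)")
  if (length(barcodes) != ncol(m)) stop("length(barcodes) != ncol(counts)")
  dimnames(m) <- list(as.character(gene_symbols), as.character(barcodes))
  if (is.null(sample_labels)) sample_labels <- character()
  if (length(sample_labels) == 1L) sample_labels <- rep(sample_labels, ncol(m))
  new("CountMatrix", m, sample_labels = as.character(sample_labels))
}

#' @export
is_count_matrix <- function(x) is(x, "CountMatrix")

#' @export
sample_labels <- function(x) if (length(x@sample_labels)) x@sample_labels else NULL

#' @export
size_factors <- function(x) x@size_factors

#' Per-cell size factors from total UMI counts
#'
#' The size factor of a cell is its total UMI count divided by the geometric
#' mean of all cells' totals (the default convention of the Monocle lineage
#' of single-cell tools), so the geometric mean of the returned factors is 1
#' and normalized values stay on the scale of the raw counts.
#'
#' @param counts A `CountMatrix`.
#' @return Named numeric vector of positive size factors, one per barcode.
#' @export
compute_size_factors <- function(counts) {
  totals <- Matrix::colSums(counts)
  zero <- totals <= 0
  if (any(zero))
    stop("cells with zero total UMI cannot be normalized: ",
         paste(colnames(counts)[zero], collapse = ", "))
  sf <- totals / exp(mean(log(totals)))
  stats::setNames(as.numeric(sf), colnames(counts))
}

#' Size-factor normalization
#'
#' Divides each cell's counts by its size factor; the sparsity pattern is
#' preserved and `normalized(g,c) * size_factor(c)` recovers the raw count
#' exactly.
#'
#' @param counts A `CountMatrix`.
#' @param size_factors Positive numeric, one per cell
#'   (default: [compute_size_factors()]).
#' @return A `NormalizedMatrix`.
#' @export
normalize_counts <- function(counts,
                             size_factors = compute_size_factors(counts)) {
  if (length(size_factors) != ncol(counts))
    stop("need one size factor per cell (", ncol(counts), "), got ",
         length(size_factors))
  if (any(size_factors <= 0)) stop("size factors must be positive")
  norm <- as(counts, "dgCMatrix") %*%
    Matrix::Diagonal(x = 1 / as.numeric(size_factors))
  norm <- as(norm, "CsparseMatrix")
  dimnames(norm) <- dimnames(counts)
  new("NormalizedMatrix", norm,
      size_factors = stats::setNames(as.numeric(size_factors), colnames(counts)),
      provenance = list(n_genes = nrow(counts), n_cells = ncol(counts)))
}

#' Per-cell QC counts and distribution summary
#'
#' Computes, per cell, the total UMI count and the number of genes detected
#' (UMI >= 1), plus the boxplot-style summary used in QC reporting: median,
#' quartiles, and 1.5 x IQR whiskers for both metrics.
#'
#' @param counts A `CountMatrix`.
#' @return List with `cells` (data.frame: barcode, total_umi,
#'   n_genes_detected), `summary` (median/quartiles/whiskers per metric) and
#'   `all_zero` flag.
#' @export
qc_summary <- function(counts) {
  total <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts >= 1)
  cells <- data.frame(barcode = colnames(counts),
                      total_umi = as.integer(total),
                      n_genes_detected = as.integer(detected),
                      stringsAsFactors = FALSE)
  five <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    c(q1 = q[1], median = q[2], q3 = q[3],
      whisker_low = max(min(x), q[1] - 1.5 * iqr),
      whisker_high = min(max(x), q[3] + 1.5 * iqr))
  }
  s <- rbind(total_umi = five(total), n_genes_detected = five(detected))
  list(cells = cells,
       summary = data.frame(metric = rownames(s), s, row.names = NULL,
                            stringsAsFactors = FALSE),
       all_zero = all(total == 0))
}
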