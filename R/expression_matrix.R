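#' Construct an ExpressionMatrix
#'
#' The central container of the package: a cells x genes expression matrix
#' (rows are cells, columns are genes) with per-cell cluster labels and an
#' optional 2-D embedding (e.g. UMAP coordinates) used for sample selection.
#'
#' @param values numeric matrix or `Matrix::dgCMatrix`, cells in rows, genes
#'   in columns. Must be non-negative.
#' @param cell_ids character vector of unique cell identifiers. Defaults to
#'   the rownames of `values`, or `cell_1 ... cell_M`.
#' @param gene_names character vector of unique gene symbols. Defaults to the
#'   colnames of `values`.
#' @param cluster_labels one categorical label per cell, or `NULL`.
#' @param embedding optional cells x 2 numeric matrix of plot coordinates.
#' @param log_transformed logical flag recording whether the values have
#'   already been log2(x+1)-transformed; [preprocess()] uses it to guarantee
#'   the transform is applied exactly once.
#'
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, cell_ids = NULL, gene_names = NULL,
                              cluster_labels = NULL, embedding = NULL,
                              log_transformed = FALSE) {
  if (!(is.matrix(values) || inherits(values, "Matrix")))
    stop("`values` must be a matrix (cells x genes)")
  m <- nrow(values); n <- ncol(values)
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(m))
  if (is.null(gene_names)) gene_names <- colnames(values)
  if (is.null(gene_names)) gene_names <- paste0("gene_", seq_len(n))
  cell_ids <- as.character(cell_ids)
  gene_names <- as.character(gene_names)
  if (length(cell_ids) != m)
    stop("length(cell_ids) != number of rows")
  if (length(gene_names) != n)
    stop("length(gene_names) != number of columns")
  if (anyDuplicated(gene_names))
    stop("gene names must be unique")
  if (!is.null(cluster_labels)) {
    cluster_labels <- as.character(cluster_labels)
    if (length(cluster_labels) != m)
      stop("one cluster label per cell is required")
  }
  if (!is.null(embedding)) {
    embedding <- as.matrix(embedding)
    if (nrow(embedding) != m || ncol(embedding) != 2L)
      stop("`embedding` must be a cells x 2 matrix")
  }
  mn <- suppressWarnings(min(values))
  if (is.finite(mn) && mn < 0)
    stop("expression values must be non-negative")
  rownames(values) <- cell_ids
  colnames(values) <- gene_names
  structure(
    list(values = values, cell_ids = cell_ids, gene_names = gene_names,
         cluster_labels = cluster_labels, embedding = embedding,
         log_transformed = isTRUE(log_transformed)),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes\n",
              length(x$cell_ids), length(x$gene_names)))
  if (!is.null(x$cluster_labels)) {
    tb <- table(x$cluster_labels)
    cat("clusters:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  }
  cat(sprintf("log-transformed: %s; embedding: %s\n",
              x$log_transformed, !is.null(x$embedding)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Restrict an ExpressionMatrix to a cell subset
#' @param em an [ExpressionMatrix][expression_matrix].
#' @param cells integer indices or character cell ids.
#' @return an `ExpressionMatrix` over the selected cells; the gene axis is
#'   left untouched.
#' @keywords internal
subset_cells <- function(em, cells) {
  if (is.character(cells)) {
    idx <- match(cells, em$cell_ids)
    if (anyNA(idx))
      stop("unknown cell ids: ", paste(utils::head(cells[is.na(idx)], 5), collapse = ", "))
  } else idx <- as.integer(cells)
  expression_matrix(
    em$values[idx, , drop = FALSE],
    cell_ids = em$cell_ids[idx],
    gene_names = em$gene_names,
    cluster_labels = if (!is.null(em$cluster_labels)) em$cluster_labels[idx],
    embedding = if (!is.null(em$embedding)) em$embedding[idx, , drop = FALSE],
    log_transformed = em$log_transformed
  )
}

#' Construct an ExpressionSample
#'
#' A labelled slice of an ExpressionMatrix: one of the two cell samples
#' entering the differential comparison.
#'
#' @param matrix an [ExpressionMatrix][expression_matrix] restricted to the
#'   selected cells.
#' @param label sample label, conventionally `"A"` or `"B"`.
#' @return an object of class `ExpressionSample` with fields `matrix`,
#'   `label` and `n_cells`.
#' @export
expression_sample <- function(matrix, label) {
  stopifnot(inherits(matrix, "ExpressionMatrix"), is.character(label),
            length(label) == 1L)
  structure(list(matrix = matrix, label = label,
                 n_cells = length(matrix$cell_ids)),
            class = "ExpressionSample")
}

#' @export
print.ExpressionSample <- function(x, ...) {
  cat(sprintf("ExpressionSample %s: %d cells x %d genes\n",
              x$label, x$n_cells, length(x$matrix$gene_names)))
  invisible(x)
}
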