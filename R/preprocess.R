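#' Preprocess an expression matrix
#'
#' Applies the standard single-cell preprocessing used throughout the
#' package, in this order:
#'
#' 1. remove genes expressed (count > 0) in fewer than
#'    `min_cell_fraction * M` cells — the comparison is a strict less-than,
#'    so a gene sitting exactly on the threshold is retained;
#' 2. keep the `n_hvg` most highly variable genes (mean-binned normalized
#'    dispersion by default, plain variance ranking as an alternative);
#' 3. log2(x+1)-transform the values, exactly once: the transform is skipped
#'    when the matrix's `log_transformed` flag is already set.
#'
#' The operation is idempotent: preprocessing an already-preprocessed matrix
#' returns it unchanged (all genes pass the expression filter, `n_hvg`
#' requests at least as many genes as remain, and the stored flag blocks a
#' second log transform).
#'
#' @param em an [ExpressionMatrix][expression_matrix] of raw or normalized
#'   counts.
#' @param min_cell_fraction minimum fraction of cells a gene must be
#'   expressed in (default 0.01).
#' @param n_hvg number of highly variable genes to retain (default 2000). If
#'   it exceeds the number of surviving genes, all survivors are kept with a
#'   warning.
#' @param hvg_method `"dispersion"` for mean-binned normalized dispersion,
#'   `"variance"` for plain variance ranking.
#' @return the preprocessed `ExpressionMatrix` (gene order preserved among
#'   retained genes, `log_transformed = TRUE`).
#' @export
preprocess <- function(em, min_cell_fraction = 0.01, n_hvg = 2000,
                       hvg_method = c("dispersion", "variance")) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  hvg_method <- match.arg(hvg_method)
  m <- length(em$cell_ids)
  vals <- em$values
  n_expressed <- if (inherits(vals, "Matrix")) Matrix::colSums(vals > 0) else colSums(vals > 0)
  keep <- n_expressed >= min_cell_fraction * m   # strict "less than" is removed
  keep <- keep & n_expressed > 0                 # guard min_cell_fraction = 0
  vals <- vals[, keep, drop = FALSE]
  if (ncol(vals) == 0L) stop("no genes survive the expression filter")

  if (n_hvg < ncol(vals)) {
    score <- hvg_score(vals, hvg_method)
    top <- rank(-score, ties.method = "first") <= n_hvg
    vals <- vals[, top, drop = FALSE]
  } else if (n_hvg > ncol(vals)) {
    warning("n_hvg (", n_hvg, ") exceeds the ", ncol(vals),
            " genes surviving the expression filter; keeping all of them")
  }

  if (!em$log_transformed) {
    vals <- as.matrix(vals)
    vals <- log2(vals + 1)
  }
  expression_matrix(vals, cell_ids = em$cell_ids,
                    gene_names = colnames(vals),
                    cluster_labels = em$cluster_labels,
                    embedding = em$embedding,
                    log_transformed = TRUE)
}

# mean-binned normalized dispersion (dispersion = var/mean, z-scored within
# 20 equal-frequency mean bins), the standard single-cell HVG statistic
hvg_score <- function(vals, method) {
  vals <- as.matrix(vals)
  mu <- colMeans(vals)
  v <- apply(vals, 2, stats::var)
  if (method == "variance") return(v)
  disp <- ifelse(mu > 0, v / mu, 0)
  nb <- max(1L, min(20L, floor(length(mu) / 5)))
  bins <- if (nb < 2L) rep(1L, length(mu)) else
    cut(rank(mu, ties.method = "first"), breaks = nb, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  z
}

#' Select the two samples to compare
#'
#' Resolves two selection specifications — each either a set of cluster
#' labels or an explicit list of cell ids — into the pair of
#' [ExpressionSample][expression_sample]s entering the differential
#' comparison. The gene axis is shared and never reordered.
#'
#' @param em an [ExpressionMatrix][expression_matrix].
#' @param spec_a,spec_b character vectors: cluster labels or cell ids.
#' @param by `"auto"` resolves each spec against cluster labels first, then
#'   cell ids; `"cluster"` or `"cell"` forces the interpretation.
#' @param allow_overlap permit the two samples to share cells (default
#'   `FALSE`: overlapping selections are an error naming the offending
#'   cells).
#' @return list with elements `a` and `b`, the two `ExpressionSample`s
#'   (labels `"A"` and `"B"`).
#' @export
select_samples <- function(em, spec_a, spec_b,
                           by = c("auto", "cluster", "cell"),
                           allow_overlap = FALSE) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  by <- match.arg(by)
  idx_a <- resolve_selection(em, spec_a, by)
  idx_b <- resolve_selection(em, spec_b, by)
  if (length(idx_a) == 0L || length(idx_b) == 0L)
    stop("empty sample selection")
  shared <- intersect(idx_a, idx_b)
  if (length(shared) > 0L && !allow_overlap)
    stop("samples overlap in ", length(shared), " cell(s) (e.g. ",
         paste(utils::head(em$cell_ids[shared], 5), collapse = ", "),
         "); set allow_overlap = TRUE to permit this")
  list(a = expression_sample(subset_cells(em, idx_a), "A"),
       b = expression_sample(subset_cells(em, idx_b), "B"))
}

resolve_selection <- function(em, spec, by) {
  spec <- as.character(spec)
  is_cluster <- !is.null(em$cluster_labels) && all(spec %in% em$cluster_labels)
  is_cell <- all(spec %in% em$cell_ids)
  use <- switch(by,
    cluster = "cluster",
    cell = "cell",
    auto = if (is_cluster) "cluster" else if (is_cell) "cell" else "none")
  if (use == "cluster") {
    if (!is_cluster) {
      bad <- setdiff(spec, unique(em$cluster_labels))
      stop("unknown cluster label(s): ", paste(utils::head(bad, 5), collapse = ", "),
           "; available: ", paste(unique(em$cluster_labels), collapse = ", "))
    }
    which(em$cluster_labels %in% spec)
  } else if (use == "cell") {
    if (!is_cell)
      stop("unknown cell id(s): ",
           paste(utils::head(setdiff(spec, em$cell_ids), 5), collapse = ", "))
    match(spec, em$cell_ids)
  } else {
    stop("selection matches neither cluster labels nor cell ids: ",
         paste(utils::head(spec, 5), collapse = ", "))
  }
}
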