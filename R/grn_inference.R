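#' Infer a weighted TF -> target network from one cell subsample
#'
#' For every non-constant gene `g`, fits a regression of `g`'s expression on
#' the expression of all transcription factors (excluding `g` itself) and
#' converts per-TF importances into directed, weighted edges:
#'
#' * `"gbm"` (default): stochastic gradient-boosted stumps with a fixed
#'   small budget (15 rounds, depth 1, learning rate 0.3, row subsample
#'   0.9); importance is total split gain. Each round spends its single
#'   split on the currently most informative TF, so unused TFs get exactly
#'   zero importance and weak regulators drop in and out across subsamples —
#'   the downstream occurrence filter exploits exactly this instability.
#' * `"extratrees"`: extremely randomized trees (impurity importance).
#' * `"correlation"`: absolute Spearman correlation; a fast deterministic
#'   engine useful for testing and for large runs.
#'
#' Importances below machine epsilon are dropped; per-target weights are
#' rescaled to sum to 1 (so weights are comparable across engines and
#' subsamples) and at most `top_regulators` TFs are retained per target,
#' by descending weight with ties broken lexicographically by TF name.
#' Finally, each TF keeps at most its `top_targets` highest-weight edges —
#' the "highest weights of each TF" become the TF's regulatory links, so a
#' regulator cannot claim an unbounded number of weak targets.
#' Rows are internally ordered by cell id before fitting, which makes the
#' result invariant to the cell order of the slice.
#'
#' @param expr numeric cells x genes matrix (one subsample slice, log scale).
#' @param tfs character vector of transcription-factor gene symbols; names
#'   absent from the matrix are ignored.
#' @param engine one of `"gbm"`, `"extratrees"`, `"correlation"`.
#' @param top_regulators maximum TFs retained per target gene (default 10).
#' @param top_targets maximum targets retained per TF (default 50), applied
#'   after the per-target retention; ties broken lexicographically by
#'   target name. `Inf` disables the cap.
#' @param seed integer seed controlling the stochastic engines.
#' @param normalize rescale retained per-target weights to sum to 1
#'   (default `TRUE`).
#' @param subsample_index index stored on the result for provenance.
#' @return a `WeightedEdgeList`: data.frame with columns `tf`, `target`,
#'   `weight`, carrying the gene universe and subsample index as attributes.
#' @export
infer_grn <- function(expr, tfs, engine = c("gbm", "extratrees", "correlation"),
                      top_regulators = 10L, top_targets = 50L, seed = 1L,
                      normalize = TRUE, subsample_index = NA_integer_) {
  engine <- match.arg(engine)
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L) stop("need at least 2 cells to infer a network")
  if (!is.null(rownames(expr)))
    expr <- expr[order(rownames(expr)), , drop = FALSE]
  genes <- colnames(expr)
  if (is.null(genes)) stop("expression slice must carry gene names")
  tfs <- intersect(tfs, genes)
  sds <- apply(expr, 2, stats::sd)
  usable_tfs <- tfs[sds[tfs] > 0]
  if (length(usable_tfs) == 0L)
    stop("no usable TFs: none present with nonzero variance in this slice")

  out <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    if (sds[g] == 0) next                       # constant target: skip
    regs <- setdiff(usable_tfs, g)
    if (length(regs) == 0L) next
    w <- switch(engine,
      correlation = importance_correlation(expr[, regs, drop = FALSE], expr[, g]),
      gbm = importance_gbm(expr[, regs, drop = FALSE], expr[, g],
                           seed = child_seed(seed, gi)),
      extratrees = importance_extratrees(expr[, regs, drop = FALSE], expr[, g],
                                         seed = child_seed(seed, gi))
    )
    w <- w[w > .Machine$double.eps]
    if (length(w) == 0L) next
    ord <- order(-w, names(w))
    w <- w[ord[seq_len(min(top_regulators, length(w)))]]
    if (normalize) w <- w / sum(w)
    out[[gi]] <- data.frame(tf = names(w), target = g, weight = unname(w),
                            stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, out)
  if (is.null(edges))
    edges <- data.frame(tf = character(), target = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  if (is.finite(top_targets) && nrow(edges) > 0) {
    keep <- unlist(lapply(split(seq_len(nrow(edges)), edges$tf), function(i) {
      ord <- i[order(-edges$weight[i], edges$target[i])]
      ord[seq_len(min(top_targets, length(ord)))]
    }), use.names = FALSE)
    edges <- edges[sort(keep), , drop = FALSE]
  }
  rownames(edges) <- NULL
  structure(edges, class = c("WeightedEdgeList", "data.frame"),
            gene_universe = genes, subsample_index = subsample_index)
}

# deterministic per-target child seed, independent of cell order
child_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 7919) %% (.Machine$integer.max - 1) + 1
}

importance_correlation <- function(X, y) {
  w <- abs(suppressWarnings(stats::cor(X, y, method = "spearman")))[, 1]
  w[is.na(w)] <- 0
  w
}

# A small fixed budget of boosting stumps: each round spends its single
# split on the currently most informative TF, so uninformative TFs receive
# exactly zero gain in most fits and their edges are unstable across
# subsamples -- the signal the occurrence filter consumes.
importance_gbm <- function(X, y, seed, nrounds = 15L) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  fit <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = 0.3, max_depth = 1,
                  subsample = 0.9, nthread = 1),
    data = dtrain, nrounds = nrounds, verbose = 0)
  w <- stats::setNames(rep(0, ncol(X)), colnames(X))
  # xgb.importance chokes on single-feature boosters; recover the gain
  # shares from the tree dump in that case
  imp <- tryCatch(xgboost::xgb.importance(model = fit), error = function(e) NULL)
  if (!is.null(imp)) {
    if (nrow(imp) > 0) w[imp$Feature] <- imp$Gain
  } else {
    tr <- xgboost::xgb.model.dt.tree(model = fit)
    tr <- tr[tr$Feature != "Leaf", , drop = FALSE]
    if (nrow(tr) > 0) {
      g <- tapply(tr$Gain, tr$Feature, sum)
      w[names(g)] <- g / sum(g)
    }
  }
  w
}

importance_extratrees <- function(X, y, seed, num_trees = 100L) {
  fit <- ranger::ranger(x = as.data.frame(X), y = y, num.trees = num_trees,
                        splitrule = "extratrees", importance = "impurity",
                        mtry = max(1L, floor(sqrt(ncol(X)))),
                        num.threads = 1, seed = seed)
  w <- fit$variable.importance
  w[w < 0] <- 0
  w
}

#' Filter an edge list with a pluggable predicate
#'
#' A generic hook point for prior-knowledge edge pruning (e.g. a
#' motif-based allowlist): edges for which the predicate returns `FALSE`
#' are removed, order is preserved. The default hook accepts everything.
#'
#' @param edges a `WeightedEdgeList` from [infer_grn()].
#' @param filter_hook function `(tf, target) -> logical(1)`; errors raised
#'   by the hook are propagated with the offending edge named.
#' @return the filtered `WeightedEdgeList`.
#' @export
apply_edge_filter <- function(edges, filter_hook = NULL) {
  if (is.null(filter_hook)) return(edges)
  stopifnot(is.function(filter_hook))
  keep <- vapply(seq_len(nrow(edges)), function(i) {
    ok <- tryCatch(isTRUE(filter_hook(edges$tf[i], edges$target[i])),
                   error = function(e)
                     stop("edge filter failed on (", edges$tf[i], " -> ",
                          edges$target[i], "): ", conditionMessage(e),
                          call. = FALSE))
    ok
  }, logical(1))
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)$gene_universe <- attr(edges, "gene_universe")
  attributes(out)$subsample_index <- attr(edges, "subsample_index")
  class(out) <- class(edges)
  out
}

#' Build an allowlist edge filter from a TSV of (tf, target) pairs
#'
#' @param path TSV file with columns `tf` and `target`.
#' @return a predicate suitable for [apply_edge_filter()]: only listed pairs
#'   pass.
#' @export
read_edge_allowlist <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  allowed <- paste(dt$tf, dt$target, sep = "\r")
  function(tf, target) paste(tf, target, sep = "\r") %in% allowed
}

#' Write a weighted edge list to TSV
#' @param edges a `WeightedEdgeList`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  dt <- data.table::as.data.table(edges)
  dt$subsample_index <- attr(edges, "subsample_index")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
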