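edge_keys <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("tf", "target") %in% names(x)))
    unique(paste(x$tf, x$target, sep = "\r"))
  } else unique(as.character(x))
}

#' Percentage of intersection between two edge sets
#'
#' `pI(N1, N2) = |N1 intersect N2| / min(|N1|, |N2|)`: the overlap of two
#' networks relative to the smaller one. Used to quantify how much of a
#' method's differential output survives replacing the true cluster labels
#' with shuffled ones — a high pI against the shuffled control means the
#' output is driven by cell-to-cell noise rather than biology.
#'
#' @param n1,n2 edge sets: data.frames with `tf` and `target` columns
#'   (directed pairs, duplicates collapsed) or plain character key vectors.
#' @return the exact fraction in \[0, 1\].
#' @export
percent_intersection <- function(n1, n2) {
  k1 <- edge_keys(n1); k2 <- edge_keys(n2)
  if (length(k1) == 0L || length(k2) == 0L)
    stop("percent_intersection is undefined for an empty edge set")
  length(intersect(k1, k2)) / min(length(k1), length(k2))
}

#' True positive rate and false discovery rate of an edge prediction
#'
#' `tpr = |predicted intersect truth| / |truth|` and
#' `fdr = |predicted \ truth| / |predicted|`. Edges are compared as directed
#' (TF -> target) pairs. An empty prediction has FDR 0 by convention (with a
#' warning), since no false discovery was made.
#'
#' @param predicted predicted edge set (data.frame with `tf`, `target`, or
#'   character keys).
#' @param truth nonempty ground-truth edge set.
#' @return list with elements `tpr`, `fdr` and `n_pred`.
#' @export
tpr_fdr <- function(predicted, truth) {
  kt <- edge_keys(truth)
  if (length(kt) == 0L) stop("truth must be nonempty")
  kp <- edge_keys(predicted)
  if (length(kp) == 0L) {
    warning("empty prediction: FDR reported as 0")
    return(list(tpr = 0, fdr = 0, n_pred = 0L))
  }
  list(tpr = length(intersect(kp, kt)) / length(kt),
       fdr = length(setdiff(kp, kt)) / length(kp),
       n_pred = length(kp))
}

#' Noise-sensitivity protocol: true versus shuffled clusters
#'
#' Runs the full differential pipeline twice on the same two-cluster matrix:
#' once comparing the true clusters, once comparing a random relabelling
#' with the original cluster sizes ([shuffle_clusters()]). Returns the
#' percentage of intersection between the two significant differential edge
#' sets. A low value means the method's output vanishes when the biological
#' grouping is destroyed, i.e. the method is robust to cell-to-cell noise.
#'
#' @param em a two-cluster [ExpressionMatrix][expression_matrix]
#'   (preprocessed).
#' @param tfs TF list used for network inference.
#' @param config a [run_config()].
#' @param seed seed for the cluster shuffle.
#' @return list with `pi` (the pI between the two edge sets), `edges_true`
#'   and `edges_shuffled` (the two significant edge tables).
#' @export
noise_sensitivity_protocol <- function(em, tfs, config = run_config(),
                                       seed = 1L) {
  labs <- unique(em$cluster_labels)
  if (length(labs) != 2L) stop("need exactly two clusters")
  run_one <- function(mat) {
    ss <- select_samples(mat, labs[1], labs[2])
    res <- run_pipeline(ss$a, ss$b, tfs, config)
    significant_edges(res$edges, config$p_cutoff)
  }
  true_edges <- run_one(em)
  shuf_edges <- run_one(shuffle_clusters(em, seed = seed))
  list(pi = percent_intersection(true_edges, shuf_edges),
       edges_true = true_edges, edges_shuffled = shuf_edges)
}

#' Write a benchmark report to JSON
#' @param report named list of metrics (e.g. from [tpr_fdr()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
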