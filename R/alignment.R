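#' Align subsample networks into a consensus network
#'
#' Collapses the `k` subsample edge lists of one sample into a single
#' consensus network. Every edge appearing in at least one subsample network
#' is retained with
#'
#' * `occurrence_rate = 100 * n_detected / k` — the percentage of subsample
#'   networks containing the edge, and
#' * `mean_weight` — the mean of its weights over the networks in which it
#'   appears (not zero-filled over all `k`).
#'
#' @param subnetworks list of `WeightedEdgeList` objects from [infer_grn()],
#'   one per subsample; their gene universes must agree.
#' @param k number of subsamples (defaults to `length(subnetworks)`).
#' @param sample_label label stored on the result (`"A"`/`"B"`).
#' @return an `AlignedNetwork`: data.frame with columns `tf`, `target`,
#'   `mean_weight`, `n_detected`, `occurrence_rate`, plus `k` and
#'   `sample_label` attributes.
#' @export
align <- function(subnetworks, k = length(subnetworks), sample_label = NA_character_) {
  stopifnot(is.list(subnetworks), length(subnetworks) >= 1L)
  if (length(subnetworks) != k)
    stop("expected ", k, " subnetworks, got ", length(subnetworks))
  universes <- lapply(subnetworks, attr, "gene_universe")
  have <- !vapply(universes, is.null, logical(1))
  if (any(have)) {
    ref <- universes[have][[1]]
    same <- vapply(universes[have], identical, logical(1), y = ref)
    if (!all(same)) stop("inconsistent gene universes across subnetworks")
  }
  all_edges <- data.table::rbindlist(
    lapply(subnetworks, function(e) data.table::as.data.table(unclass(e))))
  if (nrow(all_edges) == 0L) {
    out <- data.frame(tf = character(), target = character(),
                      mean_weight = numeric(), n_detected = integer(),
                      occurrence_rate = numeric(), stringsAsFactors = FALSE)
  } else {
    tf <- target <- weight <- NULL # appease R CMD check
    agg <- all_edges[, list(mean_weight = mean(weight),
                            n_detected = .N), by = list(tf, target)]
    agg$occurrence_rate <- 100 * agg$n_detected / k
    out <- as.data.frame(agg)
  }
  structure(out, class = c("AlignedNetwork", "data.frame"),
            k = k, sample_label = sample_label,
            gene_universe = if (any(have)) universes[have][[1]])
}

#' Filter a consensus network by edge occurrence rate
#'
#' Removes low-confidence edges: those detected in fewer subsample networks
#' than the threshold requires. The comparison keeps edges with
#' `occurrence_rate >= threshold_pct` (boundary inclusive), so a threshold of
#' 0 is the identity and 100 keeps only edges present in every subsample.
#'
#' @param net an `AlignedNetwork` from [align()].
#' @param threshold_pct occurrence threshold in \[0, 100\].
#' @return the filtered `AlignedNetwork`.
#' @export
filter_by_occurrence <- function(net, threshold_pct = 70) {
  stopifnot(inherits(net, "AlignedNetwork"),
            threshold_pct >= 0, threshold_pct <= 100)
  keep <- net$occurrence_rate >= threshold_pct
  out <- net[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)$k <- attr(net, "k")
  attributes(out)$sample_label <- attr(net, "sample_label")
  attributes(out)$gene_universe <- attr(net, "gene_universe")
  class(out) <- class(net)
  out
}

#' Assemble the cross-sample candidate pair set
#'
#' Takes the union of the two consensus edge sets. A pair absent from one
#' sample's network gets weight 0 for that sample, and every pair is
#' classified as `A_only`, `B_only` or `both`.
#'
#' @param net_a,net_b filtered `AlignedNetwork`s for samples A and B.
#' @return a `CandidatePairSet`: data.frame with columns `tf`, `target`,
#'   `w_a`, `w_b`, `presence`.
#' @export
build_candidates <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "AlignedNetwork"), inherits(net_b, "AlignedNetwork"))
  a <- data.table::data.table(tf = net_a$tf, target = net_a$target, w_a = net_a$mean_weight)
  b <- data.table::data.table(tf = net_b$tf, target = net_b$target, w_b = net_b$mean_weight)
  u <- merge(a, b, by = c("tf", "target"), all = TRUE)
  in_a <- !is.na(u$w_a); in_b <- !is.na(u$w_b)
  u$w_a[!in_a] <- 0; u$w_b[!in_b] <- 0
  u$presence <- ifelse(in_a & in_b, "both", ifelse(in_a, "A_only", "B_only"))
  out <- as.data.frame(u[order(u$tf, u$target)])
  rownames(out) <- NULL
  structure(out, class = c("CandidatePairSet", "data.frame"))
}

#' Count candidate edges by presence class
#'
#' The counts behind the A-only / B-only / shared edge Venn diagram.
#' @param candidates a `CandidatePairSet` (or any data.frame with a
#'   `presence` column).
#' @return list with integer elements `A_only`, `B_only`, `both`.
#' @export
venn_counts <- function(candidates) {
  list(A_only = sum(candidates$presence == "A_only"),
       B_only = sum(candidates$presence == "B_only"),
       both = sum(candidates$presence == "both"))
}

#' Write a consensus network to TSV
#' @param net an `AlignedNetwork`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(net, path) {
  dt <- data.table::as.data.table(unclass(net)[c("tf", "target", "mean_weight",
                                                 "occurrence_rate")])
  dt$sample <- attr(net, "sample_label")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
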