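#' Score all candidate pairs between two samples
#'
#' Attaches to every candidate (TF, target) pair:
#'
#' * `diffsco = |W_A - W_B|` — the absolute difference of the pair's
#'   consensus edge weights (0 standing in for an absent edge);
#' * `dicocopula` and `copulasimi` — the copula distance between the pair's
#'   per-sample dependence structures and its complement;
#' * `p_value` — the one-sided permutation p-value of that distance.
#'
#' Pairs with a constant expression vector in either sample are flagged
#' `degenerate` and excluded from significance calls (their `p_value` is
#' `NA`).
#'
#' @param candidates a `CandidatePairSet` from [build_candidates()].
#' @param sample_a,sample_b the two [ExpressionSample][expression_sample]s
#'   (full samples, not subsamples).
#' @param perm_cfg a [permutation_config()].
#' @param grid,m forwarded to [dicocopula()].
#' @return a `DifferentialEdgeTable`: data.frame with columns `tf`, `target`,
#'   `w_a`, `w_b`, `diffsco`, `dicocopula`, `copulasimi`, `p_value`,
#'   `presence`, `degenerate`.
#' @export
score_pairs <- function(candidates, sample_a, sample_b,
                        perm_cfg = permutation_config(), grid = "auto",
                        m = 100L) {
  va <- as.matrix(sample_a$matrix$values)
  vb <- as.matrix(sample_b$matrix$values)
  n <- nrow(candidates)
  dist <- p <- rep(NA_real_, n)
  degen <- logical(n)
  set.seed(perm_cfg$seed)
  for (i in seq_len(n)) {
    tf <- candidates$tf[i]; tg <- candidates$target[i]
    res <- suppressWarnings(
      copula_perm(va[, tf], va[, tg], vb[, tf], vb[, tg],
                  perm_cfg, grid = grid, m = m))
    dist[i] <- res$dist; p[i] <- res$p; degen[i] <- res$degenerate
  }
  if (any(degen))
    warning(sum(degen), " pair(s) with a constant marginal were flagged ",
            "degenerate and excluded from significance calls")
  out <- data.frame(
    tf = candidates$tf, target = candidates$target,
    w_a = candidates$w_a, w_b = candidates$w_b,
    diffsco = abs(candidates$w_a - candidates$w_b),
    dicocopula = dist, copulasimi = 1 - dist, p_value = p,
    presence = candidates$presence, degenerate = degen,
    stringsAsFactors = FALSE)
  structure(out, class = c("DifferentialEdgeTable", "data.frame"))
}

#' Extract and rank differential regulatory modules
#'
#' Keeps the significantly differential edges (`p_value < cutoff`, strict;
#' degenerate pairs never qualify), builds the undirected incidence graph on
#' the genes they touch, and reports each connected component as a module.
#' A module's score is the mean differential score of its member pairs, i.e.
#' the sum of the members' `diffsco` divided by the number of pairs. Modules
#' are ranked by descending score, with ties broken by size (number of
#' member pairs) and then by the lexicographically smallest member gene.
#'
#' @param edges a `DifferentialEdgeTable` from [score_pairs()].
#' @param cutoff significance level (strict `<`, default 0.05).
#' @return list of `ModuleResult` objects, each a list with `members`
#'   (sorted gene names), `edges` (the member rows), `module_diffsco`,
#'   `n_pairs` and `rank`. Zero significant edges yield an empty list.
#' @export
extract_modules <- function(edges, cutoff = 0.05) {
  sig <- edges[!edges$degenerate & !is.na(edges$p_value) &
                 edges$p_value < cutoff, , drop = FALSE]
  if (nrow(sig) == 0L) return(list())
  g <- igraph::graph_from_data_frame(sig[, c("tf", "target")], directed = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership[igraph::V(g)$name]
  mods <- lapply(seq_len(comp$no), function(ci) {
    nodes <- names(membership)[membership == ci]
    rows <- sig[sig$tf %in% nodes & sig$target %in% nodes, , drop = FALSE]
    rownames(rows) <- NULL
    structure(list(members = sort(nodes), edges = rows,
                   module_diffsco = sum(rows$diffsco) / nrow(rows),
                   n_pairs = nrow(rows), rank = NA_integer_),
              class = "ModuleResult")
  })
  score <- vapply(mods, `[[`, numeric(1), "module_diffsco")
  size <- vapply(mods, `[[`, numeric(1), "n_pairs")
  first <- vapply(mods, function(m) m$members[1], character(1))
  ord <- order(-score, -size, first)
  mods <- mods[ord]
  for (i in seq_along(mods)) mods[[i]]$rank <- i
  mods
}

#' @export
print.ModuleResult <- function(x, ...) {
  cat(sprintf("ModuleResult (rank %s): %d genes, %d pairs, DiffSco %.4f\n",
              x$rank, length(x$members), x$n_pairs, x$module_diffsco))
  cat("members:", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' Significant edges of a differential edge table
#' @param edges a `DifferentialEdgeTable`.
#' @param cutoff significance level (strict `<`).
#' @return the subset of significant, non-degenerate rows.
#' @export
significant_edges <- function(edges, cutoff = 0.05) {
  out <- edges[!edges$degenerate & !is.na(edges$p_value) &
                 edges$p_value < cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the differential edge table to TSV
#' @param edges a `DifferentialEdgeTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_differential_edges <- function(edges, path) {
  data.table::fwrite(data.table::as.data.table(edges), path, sep = "\t")
  invisible(path)
}

#' Write ranked modules to JSON and GraphML
#'
#' The JSON file lists each module's rank, score and member edges; the
#' GraphML file holds the union graph of all significant edges with the
#' per-edge presence class (`A_only`/`B_only`/`both`) as an edge attribute,
#' ready for network viewers.
#'
#' @param modules list of `ModuleResult`s from [extract_modules()].
#' @param json_path,graphml_path output paths (either may be `NULL` to skip).
#' @return invisibly, a list of the written paths.
#' @export
write_modules <- function(modules, json_path = NULL, graphml_path = NULL) {
  if (!is.null(json_path)) {
    payload <- lapply(modules, function(m)
      list(rank = m$rank, module_diffsco = m$module_diffsco,
           n_pairs = m$n_pairs, members = m$members,
           edges = m$edges[, c("tf", "target", "w_a", "w_b", "diffsco",
                               "p_value", "presence")]))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(graphml_path)) {
    all_edges <- do.call(rbind, lapply(modules, `[[`, "edges"))
    if (is.null(all_edges) || nrow(all_edges) == 0L) {
      g <- igraph::make_empty_graph()
    } else {
      g <- igraph::graph_from_data_frame(
        all_edges[, c("tf", "target", "diffsco", "p_value", "presence")],
        directed = TRUE)
    }
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(list(json = json_path, graphml = graphml_path))
}
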