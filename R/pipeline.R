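#' Pipeline configuration
#'
#' Bundles every tunable of the differential pipeline. The defaults are the
#' tool's standard operating point: 4 subsamples of 70% of the cells, a 70%
#' occurrence threshold and a 0.05 significance cutoff.
#'
#' @param k number of subsamples per sample.
#' @param pct subsample size as a percentage of the sample's cells.
#' @param occurrence_threshold consensus occurrence threshold in \[0, 100\].
#' @param p_cutoff permutation p-value significance cutoff (strict `<`).
#' @param t_permutations permutations per candidate pair.
#' @param engine GRN inference engine, see [infer_grn()].
#' @param top_regulators maximum TFs retained per target gene.
#' @param top_targets maximum targets retained per TF.
#' @param seed master seed; all stage seeds (subsampling for each sample,
#'   inference, permutations) are derived from it, so a full run is
#'   deterministic given `seed`.
#' @param grid,m copula evaluation grid, see [dicocopula()].
#' @param smooth_p use the `(count+1)/(t+1)` p-value estimator.
#' @return an object of class `RunConfig`.
#' @export
run_config <- function(k = 4L, pct = 70, occurrence_threshold = 70,
                       p_cutoff = 0.05, t_permutations = 1000L,
                       engine = c("gbm", "extratrees", "correlation"),
                       top_regulators = 10L, top_targets = 50L, seed = 1L,
                       grid = "auto", m = 100L, smooth_p = FALSE) {
  engine <- match.arg(engine)
  stopifnot(occurrence_threshold >= 0, occurrence_threshold <= 100,
            p_cutoff > 0, p_cutoff < 1)
  structure(list(k = as.integer(k), pct = pct,
                 occurrence_threshold = occurrence_threshold,
                 p_cutoff = p_cutoff, t_permutations = as.integer(t_permutations),
                 engine = engine, top_regulators = as.integer(top_regulators),
                 top_targets = top_targets,
                 seed = as.integer(seed), grid = grid, m = as.integer(m),
                 smooth_p = isTRUE(smooth_p)),
            class = "RunConfig")
}

#' Run the full differential-network pipeline on two samples
#'
#' End-to-end orchestration: draw `k` cell subsamples per sample, infer one
#' weighted TF -> target network per subsample, align each sample's networks
#' into a consensus (edge occurrence rates and mean weights), drop
#' low-occurrence edges, take the union of the two consensus networks as
#' candidate pairs, score every candidate with the copula distance plus
#' permutation p-value, and assemble ranked differential modules.
#'
#' @param sample_a,sample_b the two [ExpressionSample][expression_sample]s
#'   (log-scale expression, shared gene axis).
#' @param tfs character vector of transcription-factor symbols.
#' @param config a [run_config()].
#' @param filter_hook optional edge predicate applied to every subsample
#'   network, see [apply_edge_filter()].
#' @return a `PipelineResult` list: `consensus_a`, `consensus_b` (filtered
#'   consensus networks), `candidates`, `edges` (the differential edge
#'   table), `modules` (ranked [extract_modules()] output), `venn`
#'   (candidate counts by presence class) and `config`.
#' @export
run_pipeline <- function(sample_a, sample_b, tfs, config = run_config(),
                         filter_hook = NULL) {
  stopifnot(inherits(sample_a, "ExpressionSample"),
            inherits(sample_b, "ExpressionSample"),
            inherits(config, "RunConfig"))
  if (!identical(sample_a$matrix$gene_names, sample_b$matrix$gene_names))
    stop("samples A and B must share an identical gene axis")
  tfs <- match_tfs(tfs, sample_a$matrix)

  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 3L)

  infer_sample <- function(sample, sub_seed) {
    ss <- draw_subsamples(sample, subsample_config(config$k, config$pct, sub_seed))
    nets <- lapply(seq_len(config$k), function(i) {
      slice <- as.matrix(sample$matrix$values[ss$members[[i]], , drop = FALSE])
      net <- infer_grn(slice, tfs, engine = config$engine,
                       top_regulators = config$top_regulators,
                       top_targets = config$top_targets,
                       seed = child_seed(sub_seed, i),
                       subsample_index = i)
      apply_edge_filter(net, filter_hook)
    })
    filter_by_occurrence(align(nets, config$k, sample_label = sample$label),
                         config$occurrence_threshold)
  }
  consensus_a <- infer_sample(sample_a, stage_seeds[1])
  consensus_b <- infer_sample(sample_b, stage_seeds[2])

  candidates <- build_candidates(consensus_a, consensus_b)
  perm_cfg <- permutation_config(t = config$t_permutations,
                                 seed = stage_seeds[3],
                                 cutoff = config$p_cutoff,
                                 smooth = config$smooth_p)
  edges <- score_pairs(candidates, sample_a, sample_b, perm_cfg,
                       grid = config$grid, m = config$m)
  modules <- extract_modules(edges, config$p_cutoff)
  structure(list(consensus_a = consensus_a, consensus_b = consensus_b,
                 candidates = candidates, edges = edges, modules = modules,
                 venn = venn_counts(candidates), config = config),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  sig <- significant_edges(x$edges, x$config$p_cutoff)
  cat(sprintf(paste0("PipelineResult: %d + %d consensus edges, %d candidate ",
                     "pairs,\n  %d significant differential edges (p < %s) ",
                     "in %d module(s)\n"),
              nrow(x$consensus_a), nrow(x$consensus_b), nrow(x$candidates),
              nrow(sig), format(x$config$p_cutoff), length(x$modules)))
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Materializes a run: consensus networks, the differential edge table,
#' module JSON + GraphML, Venn counts and the resolved configuration (for
#' provenance) as plain-text files.
#'
#' @param result a `PipelineResult` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_consensus(result$consensus_a, file.path(dir, "consensus_A.tsv"))
  write_consensus(result$consensus_b, file.path(dir, "consensus_B.tsv"))
  write_differential_edges(result$edges, file.path(dir, "differential_edges.tsv"))
  write_modules(result$modules, json_path = file.path(dir, "modules.json"),
                graphml_path = file.path(dir, "modules.graphml"))
  jsonlite::write_json(result$venn, file.path(dir, "venn_counts.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(result$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
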