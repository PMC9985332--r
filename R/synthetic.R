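#' Zero-inflated negative binomial quantile function
#'
#' Quantiles of the mixture `pi0 * delta_0 + (1 - pi0) * NB(mu, size)`, the
#' marginal count model used by both simulators.
#' @param p probabilities in \[0, 1\].
#' @param mu negative binomial mean.
#' @param size negative binomial dispersion (size) parameter.
#' @param pi0 zero-inflation probability.
#' @return integer-valued counts.
#' @export
qzinb <- function(p, mu = 2, size = 1, pi0 = 0.3) {
  stopifnot(all(p >= 0 & p <= 1), pi0 >= 0, pi0 <= 1)
  if (pi0 >= 1) return(rep(0, length(p)))
  stats::qnbinom(pmax(0, (p - pi0) / (1 - pi0)), mu = mu, size = size)
}

#' Specification of a NORTA/ZINB two-cluster simulation
#'
#' Describes block-correlated zero-inflated negative binomial count data for
#' two equal cell clusters. Genes are split into consecutive blocks of
#' `group_size`; within a block the latent Gaussian correlation is
#' exchangeable. All blocks share `rho_base` in both clusters except the
#' differential block, whose correlation is `rho_diff_c1` in cluster 1
#' ("C", control) and `rho_diff_c2` in cluster 2 ("T", treatment) — the
#' induced between-cluster dependence change the pipeline is meant to
#' recover.
#'
#' @param n_cells,n_genes dimensions (equal by design; `n_cells` is split
#'   into two clusters of `n_cells / 2`).
#' @param group_size genes per correlated block (default 50).
#' @param diff_block_index which block carries the differential correlation
#'   (default 2, i.e. genes 51-100 for blocks of 50).
#' @param rho_base within-block latent correlation of non-differential
#'   blocks (default 0.6).
#' @param rho_diff_c1,rho_diff_c2 within-block latent correlation of the
#'   differential block in cluster 1 and 2 (defaults 0.8 and 0.1).
#' @param zinb_mu,zinb_size,zinb_pi shared ZINB marginal parameters
#'   (defaults mean 2, dispersion 1, zero-inflation 0.3).
#' @param seed integer seed.
#' @return an object of class `NortaSpec`.
#' @export
norta_spec <- function(n_cells = 500L, n_genes = 500L, group_size = 50L,
                       diff_block_index = 2L, rho_base = 0.6,
                       rho_diff_c1 = 0.8, rho_diff_c2 = 0.1,
                       zinb_mu = 2, zinb_size = 1, zinb_pi = 0.3, seed = 1L) {
  if (n_cells %% 2L != 0L) stop("n_cells must be even (two equal clusters)")
  n_blocks <- ceiling(n_genes / group_size)
  if (diff_block_index < 1L || diff_block_index > n_blocks)
    stop("diff_block_index out of range")
  for (r in c(rho_base, rho_diff_c1, rho_diff_c2))
    if (r < 0 || r >= 1)
      stop("exchangeable block correlations must lie in [0, 1)")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 group_size = as.integer(group_size),
                 diff_block_index = as.integer(diff_block_index),
                 rho_base = rho_base, rho_diff_c1 = rho_diff_c1,
                 rho_diff_c2 = rho_diff_c2, zinb_mu = zinb_mu,
                 zinb_size = zinb_size, zinb_pi = zinb_pi,
                 seed = as.integer(seed)),
            class = "NortaSpec")
}

# exchangeable-correlation Gaussian block via a shared factor:
# Z_ij = sqrt(rho) S_i + sqrt(1-rho) E_ij has corr(Z_j, Z_j') = rho exactly,
# and the construction is positive semidefinite for any rho in [0, 1)
rnorm_block <- function(n, p, rho) {
  s <- stats::rnorm(n)
  e <- matrix(stats::rnorm(n * p), n, p)
  sqrt(rho) * s + sqrt(1 - rho) * e
}

#' Generate NORTA/ZINB block-correlated two-cluster count data
#'
#' Draws, per cluster and per gene block, a latent standard normal block
#' with the specified exchangeable correlation, maps each coordinate through
#' the standard normal CDF to uniforms and through the ZINB quantile
#' function to counts (the NORmal-To-Anything construction, which realizes
#' arbitrary marginals under a Gaussian copula). The differential block is
#' renamed so its first gene — the block hub — is `"JUNB"` and the remaining
#' `group_size - 1` genes are its targets; every other block's first gene is
#' a named hub TF. Cells are labelled `"C"` (cluster 1) and `"T"`
#' (cluster 2).
#'
#' Note the usual NORTA caveat: the latent Gaussian correlation is distorted
#' by the discrete ZINB margins, so count-scale rank correlations are
#' attenuated relative to `rho`. This is a property of the construction and
#' is left uncorrected.
#'
#' @param spec a [norta_spec()].
#' @return list with elements `matrix` (an
#'   [ExpressionMatrix][expression_matrix] of counts with cluster labels),
#'   `truth` (a `GroundTruth` data.frame of the differential hub's edges,
#'   columns `tf`, `target`, `differential`) and `tfs` (the block hub
#'   names — the TF list to run the pipeline with).
#' @export
generate_norta <- function(spec = norta_spec()) {
  stopifnot(inherits(spec, "NortaSpec"))
  set.seed(spec$seed)
  n2 <- spec$n_cells %/% 2L
  blocks <- split(seq_len(spec$n_genes),
                  ceiling(seq_len(spec$n_genes) / spec$group_size))
  counts <- matrix(0L, spec$n_cells, spec$n_genes)
  for (cl in 1:2) {
    rows <- if (cl == 1) seq_len(n2) else n2 + seq_len(n2)
    for (b in seq_along(blocks)) {
      rho <- if (b == spec$diff_block_index) {
        if (cl == 1) spec$rho_diff_c1 else spec$rho_diff_c2
      } else spec$rho_base
      z <- rnorm_block(n2, length(blocks[[b]]), rho)
      counts[rows, blocks[[b]]] <- qzinb(stats::pnorm(z), spec$zinb_mu,
                                         spec$zinb_size, spec$zinb_pi)
    }
  }
  gene_names <- paste0("G", formatC(seq_len(spec$n_genes), width = 4, flag = "0"))
  hubs <- character(length(blocks))
  for (b in seq_along(blocks)) {
    first <- blocks[[b]][1]
    if (b == spec$diff_block_index) {
      gene_names[first] <- "JUNB"
      tg <- blocks[[b]][-1]
      gene_names[tg] <- paste0("JUNB_TG", formatC(seq_along(tg), width = 2, flag = "0"))
      hubs[b] <- "JUNB"
    } else {
      gene_names[first] <- sprintf("TF%02d", b)
      hubs[b] <- gene_names[first]
    }
  }
  labels <- rep(c("C", "T"), each = n2)
  em <- expression_matrix(counts, gene_names = gene_names,
                          cluster_labels = labels)
  diff_tg <- gene_names[blocks[[spec$diff_block_index]][-1]]
  truth <- data.frame(tf = "JUNB", target = diff_tg, differential = TRUE,
                      stringsAsFactors = FALSE)
  class(truth) <- c("GroundTruth", "data.frame")
  list(matrix = em, truth = truth, tfs = hubs)
}

#' Specification of a planted two-module ground-truth GRN simulation
#'
#' Two-cell-type count data in which a known GRN — two star modules with
#' `module_sizes` targets each — is active in one cell type and suppressed
#' in the other. In the active type each target's latent variable is a
#' linear response to its TF's latent variable plus noise; in the suppressed
#' type targets are independent noise with identical marginal moments, so
#' the two cell types differ only in dependence, never in marginals.
#'
#' @param n_genes total genes (default 250).
#' @param n_cells total cells, split into two equal cell types (paper-scale
#'   designs use 500, 2000 and 4000).
#' @param module_sizes integer vector of per-module target counts (default
#'   `c(10, 30)`, one hub TF per module).
#' @param active_cluster which cell type (1 or 2) expresses the coupling.
#' @param noise_sd standard deviation of the latent target noise relative to
#'   the unit-variance TF signal (default 0.5, i.e. a latent TF-target
#'   correlation of `1/sqrt(1 + 0.25)` ~ 0.89 before count discretization).
#' @param zinb_mu,zinb_size,zinb_pi ZINB marginal parameters.
#' @param seed integer seed.
#' @return an object of class `PlantedGRNSpec`.
#' @export
planted_grn_spec <- function(n_genes = 250L, n_cells = 500L,
                             module_sizes = c(10L, 30L), active_cluster = 1L,
                             noise_sd = 0.5, zinb_mu = 2, zinb_size = 1,
                             zinb_pi = 0.3, seed = 1L) {
  if (n_cells %% 2L != 0L) stop("n_cells must be even (two equal cell types)")
  if (length(module_sizes) < 1L || any(module_sizes < 1L))
    stop("module_sizes must be positive counts")
  if (n_genes < length(module_sizes) + sum(module_sizes))
    stop("n_genes too small for the requested modules")
  if (!active_cluster %in% 1:2) stop("active_cluster must be 1 or 2")
  structure(list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
                 module_sizes = as.integer(module_sizes),
                 active_cluster = as.integer(active_cluster),
                 noise_sd = noise_sd, zinb_mu = zinb_mu,
                 zinb_size = zinb_size, zinb_pi = zinb_pi,
                 seed = as.integer(seed)),
            class = "PlantedGRNSpec")
}

#' Generate two-cell-type data with a planted active/suppressed GRN
#'
#' @param spec a [planted_grn_spec()].
#' @return list with `matrix` (counts with cell-type labels `"type1"`,
#'   `"type2"`), `truth` (the planted TF -> target edges, all flagged
#'   differential) and `tfs` (the module hub TFs).
#' @export
generate_planted_grn <- function(spec = planted_grn_spec()) {
  stopifnot(inherits(spec, "PlantedGRNSpec"))
  set.seed(spec$seed)
  n2 <- spec$n_cells %/% 2L
  n_mod <- length(spec$module_sizes)
  tf_names <- paste0("TF", seq_len(n_mod))
  target_names <- unlist(lapply(seq_len(n_mod), function(i)
    sprintf("M%d_TG%02d", i, seq_len(spec$module_sizes[i]))))
  n_fill <- spec$n_genes - n_mod - sum(spec$module_sizes)
  fill_names <- if (n_fill > 0)
    paste0("G", formatC(seq_len(n_fill), width = 4, flag = "0")) else character()
  gene_names <- c(tf_names, target_names, fill_names)

  scale <- sqrt(1 + spec$noise_sd^2)
  latent <- matrix(0, spec$n_cells, spec$n_genes,
                   dimnames = list(NULL, gene_names))
  for (cl in 1:2) {
    rows <- if (cl == 1) seq_len(n2) else n2 + seq_len(n2)
    z_tf <- matrix(stats::rnorm(n2 * n_mod), n2, n_mod)
    latent[rows, tf_names] <- z_tf
    active <- cl == spec$active_cluster
    col <- n_mod
    for (i in seq_len(n_mod)) {
      for (j in seq_len(spec$module_sizes[i])) {
        col <- col + 1L
        eps <- stats::rnorm(n2)
        latent[rows, col] <- if (active)
          (z_tf[, i] + spec$noise_sd * eps) / scale else eps
      }
    }
    if (n_fill > 0)
      latent[rows, n_mod + sum(spec$module_sizes) + seq_len(n_fill)] <-
        stats::rnorm(n2 * n_fill)
  }
  counts <- qzinb(stats::pnorm(latent), spec$zinb_mu, spec$zinb_size,
                  spec$zinb_pi)
  counts <- matrix(counts, spec$n_cells, spec$n_genes)
  labels <- rep(c("type1", "type2"), each = n2)
  em <- expression_matrix(counts, gene_names = gene_names,
                          cluster_labels = labels)
  truth <- data.frame(
    tf = rep(tf_names, spec$module_sizes),
    target = target_names, differential = TRUE, stringsAsFactors = FALSE)
  class(truth) <- c("GroundTruth", "data.frame")
  list(matrix = em, truth = truth, tfs = tf_names)
}

#' Randomly relabel cells across two clusters
#'
#' Mixes the cells of a two-cluster matrix and splits them back into two
#' random clusters of the original sizes. Expression values, cell ids and
#' their order are untouched; only the labels move. This is the negative
#' control of the noise-sensitivity protocol: any "differential" structure
#' between the shuffled clusters is by construction noise.
#'
#' @param em an [ExpressionMatrix][expression_matrix] with exactly two
#'   cluster labels.
#' @param seed integer seed.
#' @return the relabelled `ExpressionMatrix`.
#' @export
shuffle_clusters <- function(em, seed = 1L) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  labs <- em$cluster_labels
  if (is.null(labs) || length(unique(labs)) != 2L)
    stop("shuffle_clusters needs exactly two clusters")
  set.seed(seed)
  em$cluster_labels <- sample(labs)
  em
}

#' Write a ground-truth edge list to TSV
#' @param truth a `GroundTruth` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  data.table::fwrite(data.table::as.data.table(truth), path, sep = "\t")
  invisible(path)
}
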