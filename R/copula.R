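#' Rank-based pseudo-observations of a gene pair
#'
#' Maps a pair of expression vectors to the unit square by the rank
#' transform `u_i = rank(x_i) / (n + 1)` (average ranks for ties), the
#' standard construction of the empirical copula's pseudo-observations. The
#' transform is invariant under strictly increasing changes of each
#' marginal, which is what gives every downstream copula quantity its scale
#' invariance.
#'
#' @param x,y numeric vectors of equal length (expression of a TF and of a
#'   target gene across the cells of one sample).
#' @param ties `"average"` (default) assigns tied values their average rank;
#'   `"random"` breaks ties uniformly at random (the distributional
#'   transform, whose expectation is the checkerboard copula). Randomized
#'   ties are what the differential scoring uses: single-cell counts are
#'   heavily tied at zero, and average ranks place each sample's zero atom
#'   at a sample-dependent location, so the sup-distance between two
#'   samples' copulas would measure the atom offset instead of dependence.
#'   Random tie-breaking draws from the caller's RNG stream, so results are
#'   reproducible given a seed.
#' @return an `n x 2` matrix of pairs `(u_i, v_i)` strictly inside
#'   `(0, 1)^2`, or `NULL` (with a `degenerate_marginal` warning) when either
#'   vector is constant — callers skip and report such pairs.
#' @export
pseudo_observations <- function(x, y, ties = c("average", "random")) {
  ties <- match.arg(ties)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2L) stop("need at least 2 observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning(structure(
      class = c("degenerate_marginal", "warning", "condition"),
      list(message = "constant marginal: pair skipped", call = sys.call(-1))))
    return(NULL)
  }
  cbind(u = rank(x, ties.method = ties) / (n + 1),
        v = rank(y, ties.method = ties) / (n + 1))
}

resolve_grid <- function(grid, n_total, m) {
  switch(grid,
    exact_union = 0L,
    regular = as.integer(m),
    auto = if (n_total <= 2000L) 0L else 100L,
    stop("unknown grid: ", grid))
}

#' Copula distance between a gene pair's dependence in two samples
#'
#' The Kolmogorov-Smirnov-type sup-norm distance between the two empirical
#' copulas of a (TF, target) pair: `sup |C_A(u,v) - C_B(u,v)|`, where each
#' `C` is the bivariate empirical CDF of the pair's pseudo-observations in
#' one sample. With `grid = "exact_union"` the supremum is computed exactly
#' on the product grid of all pooled pseudo-observation coordinates (where
#' the sup of a difference of step functions is attained); `"regular"`
#' evaluates on an `m x m` lattice over the unit square. `"auto"` uses the
#' exact grid when the pooled size is at most 2000 points and the lattice
#' otherwise.
#'
#' The distance is 0 for identical dependence and bounded by 1; it is
#' symmetric in the two samples and invariant under strictly increasing
#' transforms of any marginal.
#'
#' @param x_a,y_a expression vectors of the pair in sample A.
#' @param x_b,y_b expression vectors of the pair in sample B.
#' @param grid `"auto"`, `"exact_union"` or `"regular"`.
#' @param m lattice side for `grid = "regular"` (default 100).
#' @param ties tie handling of [pseudo_observations()]; the default
#'   `"random"` keeps the distance meaningful for heavily tied count data.
#' @return the distance in \[0, 1\], or `NA` when a marginal is degenerate.
#' @export
dicocopula <- function(x_a, y_a, x_b, y_b,
                       grid = c("auto", "exact_union", "regular"), m = 100L,
                       ties = "random") {
  grid <- match.arg(grid)
  pa <- pseudo_observations(x_a, y_a, ties = ties)
  pb <- pseudo_observations(x_b, y_b, ties = ties)
  if (is.null(pa) || is.null(pb)) return(NA_real_)
  gm <- resolve_grid(grid, nrow(pa) + nrow(pb), m)
  .ecop_dist_cpp(pa[, 1], pa[, 2], pb[, 1], pb[, 2], gm)
}

#' Copula similarity of a gene pair across two samples
#'
#' One minus the copula distance: 1 for identical dependence, smaller values
#' for increasingly different regulatory relationships.
#' @param distance a distance from [dicocopula()], in \[0, 1\].
#' @return `1 - distance`.
#' @export
copula_simi <- function(distance) {
  stopifnot(all(is.na(distance) | (distance >= 0 & distance <= 1)))
  1 - distance
}

#' Permutation-test configuration
#'
#' @param t number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param cutoff significance level used downstream (default 0.05).
#' @param smooth use the `(count + 1) / (t + 1)` estimator instead of the
#'   plain `count / t`, guaranteeing nonzero p-values (default `FALSE`).
#' @return an object of class `PermutationConfig`.
#' @export
permutation_config <- function(t = 1000L, seed = 1L, cutoff = 0.05,
                               smooth = FALSE) {
  t <- as.integer(t)
  if (is.na(t) || t < 1L) stop("t must be >= 1")
  if (!(cutoff > 0 && cutoff < 1)) stop("cutoff must be in (0, 1)")
  structure(list(t = t, seed = as.integer(seed), cutoff = cutoff,
                 smooth = isTRUE(smooth)),
            class = "PermutationConfig")
}

# permutation engine on raw vectors; returns dist, p and optionally the null
copula_perm <- function(x_a, y_a, x_b, y_b, cfg, grid = "auto", m = 100L,
                        ties = "random", return_null = FALSE) {
  pa <- pseudo_observations(x_a, y_a, ties = ties)
  pb <- pseudo_observations(x_b, y_b, ties = ties)
  if (is.null(pa) || is.null(pb))
    return(list(dist = NA_real_, p = NA_real_, degenerate = TRUE))
  gm <- resolve_grid(grid, nrow(pa) + nrow(pb), m)
  res <- .ecop_perm_cpp(pa[, 1], pa[, 2], pb[, 1], pb[, 2],
                        cfg$t, gm, return_null)
  p <- if (cfg$smooth) (res$n_greater + 1) / (cfg$t + 1) else res$n_greater / cfg$t
  out <- list(dist = res$dist, p = p, degenerate = FALSE)
  if (return_null) out$null <- res$null
  out
}

#' Permutation p-value for one candidate pair
#'
#' Tests whether a (TF, target) pair's dependence differs between the two
#' samples more than chance would allow. Each of `t` iterations
#' independently permutes the cell order of each gene's expression vector
#' within each sample — destroying the joint dependence while preserving both
#' marginals — and recomputes the copula similarity. The one-sided p-value is
#' the fraction of randomized similarities strictly below the observed one
#' (equivalently, randomized distances strictly above the observed
#' distance).
#'
#' @param pair character vector `c(tf, target)`.
#' @param sample_a,sample_b the two [ExpressionSample][expression_sample]s.
#' @param cfg a [permutation_config()].
#' @param grid,m forwarded to [dicocopula()].
#' @return list with elements `dist`, `p` and `degenerate`.
#' @export
permutation_pvalue <- function(pair, sample_a, sample_b,
                               cfg = permutation_config(), grid = "auto",
                               m = 100L) {
  stopifnot(length(pair) == 2L)
  va <- sample_a$matrix$values; vb <- sample_b$matrix$values
  if (!all(pair %in% colnames(va)) || !all(pair %in% colnames(vb)))
    stop("pair (", pair[1], ", ", pair[2], ") not present in both samples")
  set.seed(cfg$seed)
  copula_perm(as.numeric(va[, pair[1]]), as.numeric(va[, pair[2]]),
              as.numeric(vb[, pair[1]]), as.numeric(vb[, pair[2]]),
              cfg, grid = grid, m = m)
}
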