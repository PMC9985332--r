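# Small in-code fixtures shared across test files.

# 10 cells x 5 genes with two clusters and an embedding
tiny_matrix <- function() {
  set.seed(42)
  vals <- matrix(rpois(50, 3), nrow = 10, ncol = 5)
  expression_matrix(
    vals,
    cell_ids = paste0("c", 1:10),
    gene_names = paste0("g", 1:5),
    cluster_labels = rep(c("0", "1"), each = 5),
    embedding = matrix(rnorm(20), ncol = 2)
  )
}

# a pair of samples with planted dependence in A only
planted_samples <- function(n = 200, seed = 7) {
  set.seed(seed)
  tf <- rnorm(n)
  a_vals <- cbind(TFX = tf, TGT = tf + rnorm(n, sd = 0.3), NOISE = rnorm(n))
  b_vals <- cbind(TFX = rnorm(n), TGT = rnorm(n), NOISE = rnorm(n))
  shift <- min(a_vals, b_vals)
  a <- expression_matrix(a_vals - shift, cell_ids = paste0("a", 1:n))
  b <- expression_matrix(b_vals - shift, cell_ids = paste0("b", 1:n))
  list(a = expression_sample(a, "A"), b = expression_sample(b, "B"))
}

# brute-force sup|C_A - C_B| over the full product grid of pooled coords
brute_force_ecop_dist <- function(pa, pb) {
  us <- sort(unique(c(pa[, 1], pb[, 1])))
  vs <- sort(unique(c(pa[, 2], pb[, 2])))
  best <- 0
  for (u in us) for (v in vs) {
    ca <- mean(pa[, 1] <= u & pa[, 2] <= v)
    cb <- mean(pb[, 1] <= u & pb[, 2] <= v)
    best <- max(best, abs(ca - cb))
  }
  best
}

edge_df <- function(tf, target, weight = 1) {
  data.frame(tf = tf, target = target,
             weight = rep(weight, length.out = length(tf)),
             stringsAsFactors = FALSE)
}

as_weighted_edges <- function(df, universe = NULL, idx = NA_integer_) {
  structure(df, class = c("WeightedEdgeList", "data.frame"),
            gene_universe = universe, subsample_index = idx)
}
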