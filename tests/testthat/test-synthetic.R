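test_that("the ZINB quantile function inverts the mixture CDF", {
  mu <- 2; size <- 1; pi0 <- 0.3
  pzinb <- function(x) pi0 + (1 - pi0) * pnbinom(x, mu = mu, size = size)
  for (u in c(0.05, 0.2, 0.31, 0.5, 0.8, 0.99)) {
    q <- qzinb(u, mu, size, pi0)
    # smallest x with F(x) >= u
    expect_gte(pzinb(q), u)
    if (q > 0) expect_lt(pzinb(q - 1), u)
  }
  expect_equal(qzinb(c(0.1, 0.9), pi0 = 1), c(0, 0))
})

test_that("NORTA marginals match the ZINB parameters", {
  spec <- norta_spec(n_cells = 2000, n_genes = 100, seed = 3)
  gen <- generate_norta(spec)
  counts <- gen$matrix$values
  zero_frac <- colMeans(counts == 0)
  expected_zero <- spec$zinb_pi +
    (1 - spec$zinb_pi) * dnbinom(0, mu = spec$zinb_mu, size = spec$zinb_size)
  expect_lt(abs(mean(zero_frac) - expected_zero), 0.02)
  expected_mean <- (1 - spec$zinb_pi) * spec$zinb_mu
  expect_lt(abs(mean(colMeans(counts)) - expected_mean), 0.1)
  # pi = 1 gives an all-zero column
  gen0 <- generate_norta(norta_spec(n_cells = 100, n_genes = 100, zinb_pi = 1,
                                    seed = 1))
  expect_true(all(gen0$matrix$values == 0))
})

test_that("rho_base = 0 gives uncorrelated genes", {
  gen <- generate_norta(norta_spec(n_cells = 1000, n_genes = 100,
                                   rho_base = 0, rho_diff_c1 = 0,
                                   rho_diff_c2 = 0, seed = 4))
  counts <- gen$matrix$values[gen$matrix$cluster_labels == "C", ]
  set.seed(1)
  cors <- replicate(50, {
    ij <- sample(ncol(counts), 2)
    suppressWarnings(cor(counts[, ij[1]], counts[, ij[2]], method = "spearman"))
  })
  expect_true(all(abs(cors) < 3 / sqrt(nrow(counts))))
})

test_that("within-block correlation matches a Monte-Carlo oracle of the NORTA map", {
  spec <- norta_spec(n_cells = 4000, n_genes = 100, group_size = 50,
                     diff_block_index = 2, rho_base = 0.8, rho_diff_c1 = 0.8,
                     rho_diff_c2 = 0.8, seed = 5)
  gen <- generate_norta(spec)
  counts <- gen$matrix$values[gen$matrix$cluster_labels == "C", ]
  # observed within-block rank correlation of the first block
  set.seed(2)
  obs <- replicate(40, {
    ij <- sample(1:50, 2)
    cor(counts[, ij[1]], counts[, ij[2]], method = "spearman")
  })
  # oracle: 1e5 draws through the bivariate normal -> ZINB map
  set.seed(3)
  z1 <- rnorm(1e5); z2 <- 0.8 * z1 + sqrt(1 - 0.8^2) * rnorm(1e5)
  c1 <- qzinb(pnorm(z1), spec$zinb_mu, spec$zinb_size, spec$zinb_pi)
  c2 <- qzinb(pnorm(z2), spec$zinb_mu, spec$zinb_size, spec$zinb_pi)
  oracle <- cor(c1, c2, method = "spearman")
  expect_lt(abs(mean(obs) - oracle), 0.05)
})

test_that("only the differential block changes correlation between clusters", {
  gen <- generate_norta(norta_spec(n_cells = 1000, n_genes = 200, seed = 6))
  em <- gen$matrix
  cc <- em$values[em$cluster_labels == "C", ]
  ct <- em$values[em$cluster_labels == "T", ]
  block_cor <- function(m, b) {
    idx <- ((b - 1) * 50 + 1):(b * 50)
    cm <- suppressWarnings(cor(m[, idx], method = "spearman"))
    mean(cm[upper.tri(cm)], na.rm = TRUE)
  }
  deltas <- vapply(1:4, function(b) abs(block_cor(cc, b) - block_cor(ct, b)),
                   numeric(1))
  expect_equal(which.max(deltas), 2L)      # spec default differential block
  expect_gt(deltas[2], 0.3)
  expect_true(all(deltas[-2] < 0.1))
})

test_that("NORTA output carries the JUNB ground truth and hub TF list", {
  gen <- generate_norta(norta_spec(n_cells = 100, n_genes = 500, seed = 7))
  expect_equal(nrow(gen$truth), 49)
  expect_true(all(gen$truth$tf == "JUNB"))
  expect_length(gen$tfs, 10)
  expect_true("JUNB" %in% gen$tfs)
  expect_true(all(gen$truth$target %in% gen$matrix$gene_names))
  expect_setequal(unique(gen$matrix$cluster_labels), c("C", "T"))
  # determinism
  gen2 <- generate_norta(norta_spec(n_cells = 100, n_genes = 500, seed = 7))
  expect_identical(gen$matrix$values, gen2$matrix$values)
})

test_that("planted GRN couples targets to TFs in the active type only", {
  spec <- planted_grn_spec(n_genes = 60, n_cells = 600,
                           module_sizes = c(4, 6), noise_sd = 0.01, seed = 8)
  gen <- generate_planted_grn(spec)
  expect_equal(nrow(gen$truth), 10)
  active <- gen$matrix$values[gen$matrix$cluster_labels == "type1", ]
  suppressed <- gen$matrix$values[gen$matrix$cluster_labels == "type2", ]
  r_act <- cor(active[, "TF1"], active[, "M1_TG01"], method = "spearman")
  r_sup <- cor(suppressed[, "TF1"], suppressed[, "M1_TG01"],
               method = "spearman")
  expect_gt(r_act, 0.8)              # near-deterministic coupling, ZINB-attenuated
  expect_lt(abs(r_sup), 0.15)
  # matched marginals: zero fractions agree between cell types
  expect_lt(abs(mean(active == 0) - mean(suppressed == 0)), 0.02)
})

test_that("the default planted design matches the two-module shape", {
  spec <- planted_grn_spec()
  expect_equal(spec$n_genes, 250L)
  expect_equal(spec$module_sizes, c(10L, 30L))
  gen <- generate_planted_grn(planted_grn_spec(n_cells = 100, seed = 9))
  expect_equal(nrow(gen$truth), 40)  # 10 + 30 ground-truth edges
  expect_equal(gen$tfs, c("TF1", "TF2"))
})

test_that("cluster shuffling preserves sizes and cell identity", {
  vals <- matrix(rpois(300, 2), nrow = 100)
  em <- expression_matrix(vals, cluster_labels = rep(c("x", "y"), c(30, 70)))
  sh <- shuffle_clusters(em, seed = 5)
  expect_equal(as.vector(table(sh$cluster_labels)[c("x", "y")]), c(30, 70))
  expect_identical(sh$cell_ids, em$cell_ids)
  expect_identical(sh$values, em$values)
  expect_identical(shuffle_clusters(em, seed = 5)$cluster_labels,
                   sh$cluster_labels)
  expect_error(shuffle_clusters(expression_matrix(vals), 1), "two clusters")
})
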