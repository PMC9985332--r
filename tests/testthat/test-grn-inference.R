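sim_slice <- function(n = 200, seed = 1) {
  set.seed(seed)
  tf1 <- rnorm(n); tf2 <- rnorm(n); tf3 <- rnorm(n)
  tgt <- 2 * tf1 + rnorm(n, sd = 0.1)
  m <- cbind(TF1 = tf1, TF2 = tf2, TF3 = tf3, TGT = tgt)
  m <- m - min(m)
  rownames(m) <- paste0("c", seq_len(n))
  m
}

test_that("correlation engine equals the absolute Spearman oracle", {
  m <- sim_slice(60)
  net <- infer_grn(m, c("TF1", "TF2", "TF3"), engine = "correlation",
                   normalize = FALSE)
  for (i in seq_len(nrow(net))) {
    oracle <- abs(cor(m[, net$tf[i]], m[, net$target[i]], method = "spearman"))
    expect_equal(net$weight[i], oracle, tolerance = 1e-12)
  }
  # ordering: strong vs weak regulator
  set.seed(2)
  n <- 300
  tf1 <- rnorm(n)
  tgt <- tf1 + rnorm(n, sd = 0.4)            # |spearman| high
  tf2 <- rnorm(n)                            # |spearman| ~ 0
  m2 <- cbind(TF1 = tf1, TF2 = tf2, TGT = tgt) - min(tf1, tgt, tf2)
  net2 <- infer_grn(m2, c("TF1", "TF2"), engine = "correlation")
  w <- net2[net2$target == "TGT", ]
  expect_gt(w$weight[w$tf == "TF1"], w$weight[w$tf == "TF2"])
})

test_that("a copied TF dominates the target's importances in every engine", {
  for (eng in c("correlation", "gbm", "extratrees")) {
    m <- sim_slice(200, seed = 3)
    net <- infer_grn(m, c("TF1", "TF2", "TF3"), engine = eng, seed = 11)
    w <- net[net$target == "TGT", ]
    expect_equal(w$tf[which.max(w$weight)], "TF1", info = eng)
  }
})

test_that("ensemble engines pick the planted regulator over decoys in nearly all seeds", {
  hits <- c(gbm = 0L, extratrees = 0L)
  n_seeds <- 20
  for (seed in seq_len(n_seeds)) {
    set.seed(seed + 100)
    n <- 300
    tf1 <- rnorm(n)
    decoys <- matrix(rnorm(n * 4), n, 4,
                     dimnames = list(NULL, paste0("D", 1:4)))
    tgt <- 2 * tf1 + rnorm(n)
    m <- cbind(TF1 = tf1, decoys, TGT = tgt)
    m <- m - min(m)
    for (eng in names(hits)) {
      net <- infer_grn(m, c("TF1", paste0("D", 1:4)), engine = eng, seed = seed)
      w <- net[net$target == "TGT", ]
      if (w$tf[which.max(w$weight)] == "TF1")
        hits[eng] <- hits[eng] + 1L
    }
  }
  expect_gte(hits[["gbm"]], ceiling(0.95 * n_seeds))
  expect_gte(hits[["extratrees"]], ceiling(0.95 * n_seeds))
})

test_that("weights are invariant to permuting cell order within a subsample", {
  m <- sim_slice(150, seed = 5)
  for (eng in c("correlation", "gbm", "extratrees")) {
    net1 <- infer_grn(m, c("TF1", "TF2", "TF3"), engine = eng, seed = 2)
    set.seed(99)
    perm <- sample(nrow(m))
    net2 <- infer_grn(m[perm, ], c("TF1", "TF2", "TF3"), engine = eng, seed = 2)
    expect_equal(net1, net2, ignore_attr = TRUE, info = eng)
  }
})

test_that("per-target and per-TF retention caps apply with lexicographic ties", {
  m <- sim_slice(100, seed = 6)
  net <- infer_grn(m, c("TF1", "TF2", "TF3"), engine = "correlation",
                   top_regulators = 1)
  expect_true(all(table(net$target) <= 1))
  net2 <- infer_grn(m, c("TF1", "TF2", "TF3"), engine = "correlation",
                    top_targets = 1)
  expect_true(all(table(net2$tf) <= 1))
  # tie in weight: lexicographically smaller TF wins
  ties <- as_weighted_edges(edge_df(c("B", "A"), c("t", "t"), c(0.5, 0.5)))
  ord <- order(-ties$weight, ties$tf)
  expect_identical(ties$tf[ord][1], "A")
})

test_that("normalized per-target weights sum to one", {
  m <- sim_slice(100, seed = 8)
  net <- infer_grn(m, c("TF1", "TF2", "TF3"), engine = "correlation")
  sums <- tapply(net$weight, net$target, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("degenerate inputs raise or skip as specified", {
  m <- sim_slice(50)
  expect_error(infer_grn(m, "ZZZ"), "no usable TFs")
  m2 <- cbind(m, FLAT = rep(1, nrow(m)))
  net <- infer_grn(m2, c("TF1", "FLAT"), engine = "correlation")
  expect_false("FLAT" %in% net$target)     # constant target skipped
  expect_false("FLAT" %in% net$tf)         # zero-variance TF unusable
  expect_error(infer_grn(m[1, , drop = FALSE], "TF1"), "2 cells")
})

test_that("edge filters: default identity, predicate rejection, allowlist intersection", {
  edges <- as_weighted_edges(edge_df(c("X", "Y", "X"), c("t1", "t2", "t3"),
                                     c(0.5, 0.4, 0.3)))
  expect_identical(apply_edge_filter(edges, NULL), edges)
  no_x <- apply_edge_filter(edges, function(tf, target) tf != "X")
  expect_identical(no_x$tf, "Y")

  path <- file.path(withr::local_tempdir(), "allow.tsv")
  writeLines(c("tf\ttarget", "X\tt1", "Y\tt2", "Q\tq1"), path)
  hook <- read_edge_allowlist(path)
  kept <- apply_edge_filter(edges, hook)
  # brute-force set intersection
  expect_setequal(paste(kept$tf, kept$target),
                  intersect(paste(edges$tf, edges$target),
                            c("X t1", "Y t2", "Q q1")))
  expect_error(apply_edge_filter(edges, function(tf, target) stop("boom")),
               "X -> t1")
})
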