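test_that("pseudo-observations are rank/(n+1) with average ranks for ties", {
  p <- pseudo_observations(c(1, 2, 3), c(3, 2, 1))
  expect_equal(p[, "u"], c(0.25, 0.5, 0.75))
  expect_equal(p[, "v"], c(0.75, 0.5, 0.25))
  # two tied minima among n = 4: average rank 1.5 -> 1.5/5
  p2 <- pseudo_observations(c(0, 0, 2, 3), c(1, 2, 3, 4))
  expect_equal(p2[1:2, "u"], c(0.3, 0.3))
  # invariance under a strictly increasing transform
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(pseudo_observations(exp(x), y), pseudo_observations(x, y))
})

test_that("constant marginals trigger the degenerate warning and a skip", {
  expect_warning(out <- pseudo_observations(rep(1, 10), rnorm(10)),
                 class = "degenerate_marginal")
  expect_null(out)
  expect_true(is.na(suppressWarnings(
    dicocopula(rep(1, 10), rnorm(10), rnorm(10), rnorm(10)))))
})

test_that("identical samples have distance zero and similarity one", {
  x <- rnorm(100); y <- rnorm(100)
  d <- dicocopula(x, y, x, y)
  expect_equal(d, 0)
  expect_equal(copula_simi(d), 1)
  expect_equal(copula_simi(0.25), 0.75)
  expect_equal(copula_simi(0.5), 0.5)
})

test_that("distance attains the analytic limits for canonical dependence patterns", {
  set.seed(31)
  n <- 2000
  x <- rnorm(n)
  # comonotone vs independent: sup |min(u,v) - uv| = 1/4 at u = v = 1/2
  d1 <- dicocopula(x, x, rnorm(n), rnorm(n))
  expect_lt(abs(d1 - 0.25), 0.05)
  # comonotone vs countermonotone: Frechet-Hoeffding bounds, sup = 1/2
  d2 <- dicocopula(x, x, x, -x)
  expect_lt(abs(d2 - 0.5), 0.01)
})

test_that("distance is symmetric, bounded, and within the Frechet envelope", {
  set.seed(32)
  for (i in 1:5) {
    n <- 500
    xa <- rnorm(n); ya <- xa * i / 5 + rnorm(n)
    xb <- rnorm(n); yb <- -xb * (5 - i) / 5 + rnorm(n)
    set.seed(i); dab <- dicocopula(xa, ya, xb, yb)
    set.seed(i); dba <- dicocopula(xb, yb, xa, ya)
    expect_equal(dab, dba)
    expect_gte(dab, 0)
    expect_lte(dab, 0.5 + 0.05)
  }
})

test_that("the exact union evaluator equals the brute-force product-grid oracle", {
  set.seed(33)
  for (i in 1:10) {
    na <- sample(5:50, 1); nb <- sample(5:50, 1)
    # include heavily tied count data, where ties are the hard case
    if (i <= 5) {
      xa <- rnorm(na); ya <- rnorm(na); xb <- rnorm(nb); yb <- rnorm(nb)
    } else {
      xa <- rpois(na, 1); ya <- rpois(na, 1); xb <- rpois(nb, 2); yb <- rpois(nb, 2)
      if (length(unique(xa)) < 2 || length(unique(ya)) < 2 ||
          length(unique(xb)) < 2 || length(unique(yb)) < 2) next
    }
    pa <- pseudo_observations(xa, ya)
    pb <- pseudo_observations(xb, yb)
    expect_equal(diffgrn:::.ecop_dist_cpp(pa[, 1], pa[, 2], pb[, 1], pb[, 2], 0L),
                 brute_force_ecop_dist(pa, pb), tolerance = 1e-12)
  }
})

test_that("the regular lattice approximates the exact distance", {
  set.seed(34)
  x <- rnorm(400)
  d_exact <- dicocopula(x, x, rnorm(400), rnorm(400), grid = "exact_union")
  d_grid <- dicocopula(x, x, rnorm(400), rnorm(400), grid = "regular", m = 100)
  expect_lt(abs(d_exact - d_grid), 0.05)
})

test_that("the distance is exactly invariant under strictly increasing marginal transforms", {
  set.seed(35)
  xa <- rnorm(80); ya <- xa + rnorm(80); xb <- rnorm(70); yb <- rnorm(70)
  base <- dicocopula(xa, ya, xb, yb, ties = "average")
  expect_identical(dicocopula(exp(xa), ya, xb, yb, ties = "average"), base)
  expect_identical(dicocopula(xa, ya^3 + 2 * ya, xb, yb, ties = "average"), base)
  expect_identical(dicocopula(xa, ya, 5 * xb - 1, atan(yb), ties = "average"),
                   base)
})

test_that("permutation p-value matches its counting formula (strict inequality)", {
  set.seed(36)
  xa <- rnorm(60); ya <- xa + rnorm(60, sd = 0.2)
  xb <- rnorm(60); yb <- rnorm(60)
  cfg <- permutation_config(t = 200, seed = 4)
  set.seed(cfg$seed)
  res <- diffgrn:::copula_perm(xa, ya, xb, yb, cfg, return_null = TRUE)
  expect_equal(res$p, sum(res$null > res$dist) / cfg$t)
  # smooth estimator
  cfg2 <- permutation_config(t = 200, seed = 4, smooth = TRUE)
  set.seed(cfg2$seed)
  res2 <- diffgrn:::copula_perm(xa, ya, xb, yb, cfg2, return_null = TRUE)
  expect_equal(res2$p, (sum(res2$null > res2$dist) + 1) / (cfg2$t + 1))
  expect_gt(res2$p, 0)
})

test_that("p-values are uniform under the null", {
  # the strict-< counting estimator is deflated by half the tie mass of the
  # discrete distance, so uniformity is asserted at a sample size where the
  # distance atoms are fine (tie mass ~1%); the rejection rate at the 0.05
  # operating point is already nominal from a few hundred cells on
  set.seed(37)
  cfg <- permutation_config(t = 200, seed = 0)
  n <- 1000
  ps <- replicate(500, {
    diffgrn:::copula_perm(rnorm(n), rnorm(n), rnorm(n), rnorm(n), cfg)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
  # rejection rate at 0.05 close to nominal (binomial 3-sigma ~ 0.029)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
  set.seed(39)
  ps250 <- replicate(300, {
    diffgrn:::copula_perm(rnorm(250), rnorm(250), rnorm(250), rnorm(250), cfg)$p
  })
  expect_lt(abs(mean(ps250 < 0.05) - 0.05), 0.04)
})

test_that("the test has power against a real dependence change", {
  set.seed(38)
  cfg <- permutation_config(t = 200, seed = 0)
  hits <- 0L
  n_rep <- 40
  for (i in seq_len(n_rep)) {
    x <- rnorm(250)
    p <- diffgrn:::copula_perm(x, x, rnorm(250), rnorm(250), cfg)$p
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_rep))
})

test_that("permutation_pvalue works on named pairs from samples", {
  ps <- planted_samples()
  res <- permutation_pvalue(c("TFX", "TGT"), ps$a, ps$b,
                            permutation_config(t = 200, seed = 3))
  expect_lt(res$p, 0.05)
  res_null <- permutation_pvalue(c("TFX", "NOISE"), ps$a, ps$b,
                                 permutation_config(t = 200, seed = 3))
  expect_gt(res_null$p, 0.01)
  expect_error(permutation_pvalue(c("TFX", "nope"), ps$a, ps$b), "not present")
})
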