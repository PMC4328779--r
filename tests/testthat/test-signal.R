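test_that("K equals 1 exactly on star trees and matches a dense-algebra oracle", {
  st <- star_tree(16, depth = 2)
  set.seed(31)
  x <- stats::setNames(rnorm(16), st$tip.label)
  expect_equal(blomberg_k(st, x), 1, tolerance = 1e-12)

  t4 <- tree4()
  x4 <- c(A = 1, B = 2, C = 4, D = 8)
  expect_equal(blomberg_k(t4, x4), dense_k(phylo_vcv(t4), x4[t4$tip.label]),
               tolerance = 1e-12)
  # and against the established implementation on a larger instance
  tr <- simulate_tree(40, seed = 32)
  x40 <- simulate_trait(tr, "lambda", lambda = 0.6, seed = 33)
  expect_equal(blomberg_k(tr, x40),
               as.numeric(picante::Kcalc(x40[tr$tip.label], tr)),
               tolerance = 1e-8)
  expect_error(blomberg_k(tr, stats::setNames(rep(1, 40), tr$tip.label)),
               "constant")
})

test_that("K and lambda are invariant to affine transformation of the trait", {
  tr <- simulate_tree(48, seed = 34)
  x <- simulate_trait(tr, "lambda", lambda = 0.5, seed = 35)
  for (ab in list(c(3, 2), c(-1, 0.1), c(100, 50))) {
    y <- ab[1] + ab[2] * x
    expect_equal(blomberg_k(tr, y), blomberg_k(tr, x), tolerance = 1e-9)
    expect_equal(pagel_lambda(tr, y)$lambda, pagel_lambda(tr, x)$lambda,
                 tolerance = 1e-5)
  }
})

test_that("lambda ML matches a fine grid search and dominates the endpoints", {
  tr <- simulate_tree(24, seed = 36)
  C <- phylo_vcv(tr)
  x <- simulate_trait(tr, "lambda", lambda = 0.4, seed = 37)
  fit <- pagel_lambda(tr, x)
  grid <- seq(0, 1, length.out = 2001)
  ll <- vapply(grid, function(l) phylosong:::lambda_profile_logL(
    as.numeric(x[tr$tip.label]), C, l), numeric(1))
  expect_equal(fit$lambda, grid[which.max(ll)], tolerance = 1e-3)
  expect_gte(fit$logL, max(ll) - 1e-8)
  expect_gte(fit$logL, ll[1])     # lambda = 0
  expect_gte(fit$logL, ll[2001])  # lambda = 1
  # agreement with the established ML implementation
  ph <- phytools::phylosig(tr, x, method = "lambda")
  expect_gte(fit$logL, ph$logL - 1e-6)  # our profile optimum is no worse
  expect_equal(fit$lambda, ph$lambda, tolerance = 1e-2)
})

test_that("lambda estimates separate tree-free from Brownian data", {
  tr <- simulate_tree(128, seed = 38)
  set.seed(39)
  lam_white <- replicate(100, pagel_lambda(
    tr, stats::setNames(rnorm(128), tr$tip.label))$lambda)
  expect_lt(median(lam_white), 0.1)
  X <- simulate_trait(tr, "BM", nsim = 100, seed = 40)
  lam_bm <- apply(X, 1, function(x) pagel_lambda(tr, x)$lambda)
  expect_gt(median(lam_bm), 0.9)
})

test_that("K of lambda-generated data increases with the generating lambda", {
  tr <- simulate_tree(80, seed = 41)
  med_k <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(l) {
    X <- simulate_trait(tr, "lambda", lambda = l, nsim = 200, seed = 42 + round(100 * l))
    median(apply(X, 1, function(x) blomberg_k(tr, x)))
  }, numeric(1))
  expect_true(all(diff(med_k) > 0))
})

test_that("randomization P is seed-reproducible with the documented floor", {
  tr <- simulate_tree(64, seed = 43)
  x <- simulate_trait(tr, "BM", seed = 44)
  r1 <- signal_randomization(tr, x, n_perm = 199, seed = 7)
  r2 <- signal_randomization(tr, x, n_perm = 199, seed = 7)
  expect_identical(r1$P, r2$P)
  expect_identical(r1$perm_stats, r2$perm_stats)
  expect_gte(r1$P, 1 / 200)

  # strongly tree-structured data pin P at the attainable floor
  tr128 <- simulate_tree(128, seed = 45)
  X <- simulate_trait(tr128, "BM", nsim = 20, seed = 46)
  ps <- vapply(seq_len(20), function(i) {
    signal_randomization(tr128, X[i, ], n_perm = 999, seed = 100 + i)$P
  }, numeric(1))
  expect_gte(mean(ps == 0.001), 0.95)
})

test_that("randomization test holds its nominal size under a shuffled null", {
  tr <- simulate_tree(64, seed = 47)
  X <- simulate_trait(tr, "BM", nsim = 1000, seed = 48)
  set.seed(49)
  rej <- vapply(seq_len(1000), function(i) {
    x <- stats::setNames(sample(X[i, ]), tr$tip.label)  # break tree structure
    signal_randomization(tr, x, n_perm = 99)$P <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("per-trait signal table carries K, P and lambda for each trait", {
  st <- small_study(seed = 51, n_taxa = 16)
  tt <- build_trait_table(st$verses, st$explanatory)
  sig <- phylo_signal(tt, st$tree, c("tges", "fmean"), n_perm = 99, seed = 3)
  expect_equal(sig$trait, c("tges", "fmean"))
  expect_true(all(sig$K > 0))
  expect_true(all(sig$P >= 0.01 & sig$P <= 1))
  expect_true(all(sig$lambda >= 0 & sig$lambda <= 1))
  sig2 <- phylo_signal(tt, st$tree, c("tges", "fmean"), n_perm = 99, seed = 3)
  expect_identical(sig, sig2)
})
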