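test_that("simulated trees are binary, ultrametric and seed-reproducible", {
  t2 <- simulate_tree(2, seed = 121)
  expect_length(t2$tip.label, 2)
  expect_true(attr(t2, "ultrametric"))
  expect_identical(write_song_tree(simulate_tree(12, seed = 122)),
                   write_song_tree(simulate_tree(12, seed = 122)))
  # a binary tree on n tips always has n - 1 internal nodes
  nn <- vapply(1:20, function(i) simulate_tree(80, seed = 300 + i)$Nnode,
               numeric(1))
  expect_true(all(nn == 79))
  d <- tip_depths(simulate_tree(30, seed = 123, depth = 2.5))
  expect_equal(unname(max(d)), 2.5, tolerance = 1e-9)
})

test_that("trait simulation matches the model variances it claims", {
  tr <- simulate_tree(40, seed = 124, depth = 1)
  X <- simulate_trait(tr, "BM", sigma2 = 1, nsim = 1000, seed = 125)
  # tip variance under BM on a depth-1 tree is sigma2
  expect_equal(mean(apply(X, 2, stats::var)), 1, tolerance = 0.1)
  # white-noise traits carry no correlation between any tips, sisters included
  Xw <- simulate_trait(tr, "white", nsim = 1000, seed = 126)
  expect_lt(abs(stats::cor(Xw[, 1], Xw[, 2])), 0.1)
  expect_identical(simulate_trait(tr, "BM", seed = 127),
                   simulate_trait(tr, "BM", seed = 127))
})

test_that("generating lambda is recovered by the profile-ML estimator", {
  tr <- simulate_tree(200, seed = 128)
  X <- simulate_trait(tr, "lambda", lambda = 0.5, nsim = 100, seed = 129)
  lam <- apply(X, 1, function(x) pagel_lambda(tr, x)$lambda)
  expect_lt(abs(median(lam) - 0.5), 0.15)
})

test_that("synthetic studies respect the sampling design and all invariants", {
  st <- simulate_study(synth_config(), seed = 131)
  expect_length(st$tree$tip.label, 80)
  expect_invisible(validate_verses(st$verses))
  expect_invisible(validate_explanatory(st$explanatory))
  per <- dplyr::count(st$verses, taxon, individual)
  expect_lte(max(per$n), 10)
  expect_true(all(per$n %in% c(5, 10)))
  per_taxon <- dplyr::n_distinct(st$verses$individual)
  expect_lte(per_taxon, 5)
  # value ranges stay inside the reference envelopes
  expect_true(all(st$verses$tges >= 0.46 & st$verses$tges <= 5.31))
  expect_true(all(st$verses$fmax <= 14 & st$verses$fmin >= 1.2))
  # cohort score means mirror the reference counts by construction
  s <- summarize_cohort(st$explanatory, c("migration", "habitat"))
  expect_equal(round(s$mean[s$variable == "migration"], 1), 1.3)
  expect_equal(round(s$mean[s$variable == "habitat"], 1), 4.1)
})

test_that("studies are bit-reproducible and the ground truth is complete", {
  a <- simulate_study(synth_config(n_taxa = 20), seed = 132)
  b <- simulate_study(synth_config(n_taxa = 20), seed = 132)
  expect_identical(a$verses, b$verses)
  expect_identical(a$explanatory, b$explanatory)
  expect_identical(write_song_tree(a$tree), write_song_tree(b$tree))
  expect_named(a$truth,
               c("seed", "models", "body_size_slope", "latent_values",
                 "large_repertoire", "tempo_norm"))
  dir <- withr::local_tempdir()
  write_study(a, dir)
  expect_setequal(list.files(dir),
                  c("tree.nwk", "verses.tsv", "explanatory.tsv", "truth.txt"))
  back <- read_study(dir)
  expect_equal(as.data.frame(back$verses), as.data.frame(a$verses),
               tolerance = 1e-9)
  expect_setequal(back$tree$tip.label, a$tree$tip.label)
})

test_that("the planted body-size effect is recovered by the pGLS stage", {
  # Sign recovery of the planted -0.3 kHz/cm frequency effect. Power is
  # bounded by the fully tree-structured residuals of the generator (both
  # predictor and residual evolve on the same phylogeny), so the large
  # majority, not near-certainty, is the calibrated expectation here; the
  # near-certain sign-recovery check under Brownian residuals lives in the
  # acceptance suite.
  hit <- vapply(seq_len(100), function(i) {
    st <- simulate_study(synth_config(), seed = 2000 + i)
    tt <- suppressMessages(build_trait_table(st$verses, st$explanatory))
    pg <- pgls_fit(tt, st$tree, fmean ~ length, lambda = "ML")
    pg$coefficients$estimate[2] < 0
  }, logical(1))
  expect_gte(mean(hit), 0.85)
})

test_that("an all-Brownian noise-free study yields Brownian-looking signal", {
  cfg <- synth_config(
    noise_indiv = 0, noise_verse = 0, body_size_slope = 0,
    models = sapply(names(phylosong:::default_latent_models()),
                    function(n) list(model = "BM"), simplify = FALSE))
  km <- vapply(1:10, function(i) {
    s2 <- simulate_study(cfg, seed = 600 + i)
    tt <- suppressMessages(build_trait_table(s2$verses, s2$explanatory))
    mean(vapply(c("fmin", "df", "dfmin", "fmodend"), function(tr) {
      blomberg_k(s2$tree, stats::setNames(tt[[tr]], tt$taxon))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean(km), 0.8)
  expect_lt(mean(km), 1.2)
})
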