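make_verses <- function(n_taxa = 3, ind = 2, verse = 2, seed = 5) {
  set.seed(seed)
  g <- expand.grid(taxon = paste0("t", seq_len(n_taxa)),
                   individual = seq_len(ind), verse = seq_len(verse),
                   stringsAsFactors = FALSE)
  tges <- runif(nrow(g), 1, 4)
  tmax <- tges * runif(nrow(g), 0.05, 0.5)
  zel <- pmax(1, round(tges * runif(nrow(g), 2, 12)))
  fmin <- runif(nrow(g), 2, 4)
  dfmin <- runif(nrow(g), 0.7, 2)
  tibble::as_tibble(data.frame(
    g, tges = tges, tmax = tmax, tmin = tmax * runif(nrow(g), 0.3, 1),
    zel = zel, zeltype = pmax(1, round(zel * runif(nrow(g), 0.2, 1))),
    fmin = fmin, fmax = fmin + runif(nrow(g), 2, 5),
    dfmin = dfmin, dfmax = dfmin * runif(nrow(g), 1, 2.5),
    fmodend = rnorm(nrow(g), 0, 0.8)
  ))
}

test_that("verse-level derivations follow the defining formulas", {
  v <- make_verses()[1, ]
  v$fmin <- 3; v$fmax <- 7
  d <- derive_song_traits(v)
  expect_equal(d$fmean, 5)
  expect_equal(d$df, 4)
  expect_equal(d$zeltges, v$zel / v$tges)
  expect_equal(d$complexity2, v$zeltype / v$zel)

  # identical element bandwidths and durations pin complexity1 at its floor
  v2 <- v
  v2$dfmax <- v2$dfmin <- 1.5
  v2$tmax <- v2$tmin <- 0.2
  expect_equal(derive_song_traits(v2)$complexity1, 1)

  # a verse at the normalising tempo gets tempo component exactly 1
  v3 <- v
  v3$tges <- 1; v3$tmax <- 0.2; v3$tmin <- 0.1
  v3$zel <- 30.268; v3$zeltype <- 10
  d3 <- derive_song_traits(v3)
  expect_equal(d3$complexity3 - d3$complexity2, 1)
})

test_that("derived complexity indices respect their analytic bounds", {
  d <- derive_song_traits(make_verses(8, 3, 4, seed = 6))
  expect_true(all(d$complexity1 >= 1))
  expect_true(all(d$complexity2 > 0 & d$complexity2 <= 1))
  expect_true(all(d$complexity3 > 0))
  expect_true(all(d$fmean > d$fmin & d$fmean < d$fmax))
  expect_true(all(d$df > 0))
})

test_that("verse-table invariant violations are rejected", {
  v <- make_verses()
  bad <- v; bad$tmin[1] <- bad$tges[1] * 2
  expect_error(validate_verses(bad), "tges >= tmax")
  bad <- v; bad$zeltype[2] <- bad$zel[2] + 1
  expect_error(validate_verses(bad), "zel >= zeltype")
  bad <- v; bad$fmin[1] <- bad$fmax[1]
  expect_error(validate_verses(bad), "fmax > fmin")
})

test_that("taxon means average individuals, not pooled verses", {
  v <- tibble::tibble(
    taxon = "t1", individual = c(1, 1, 1, 2), verse = c(1, 2, 3, 1),
    tges = c(1, 2, 3, 5)
  )
  out <- aggregate_taxon_means(v, traits = "tges")
  expect_equal(out$tges, 3.5)  # (mean(1,2,3) + 5) / 2, not 11/4

  v1 <- v[1, ]
  expect_equal(aggregate_taxon_means(v1, traits = "tges")$tges, 1)
  expect_error(aggregate_taxon_means(v[0, ], traits = "tges"), "empty")
})

test_that("aggregation matches a brute-force group-by-twice oracle and ignores row order", {
  set.seed(9)
  v <- derive_song_traits(make_verses(6, 3, 5, seed = 7))
  v <- v[sample(nrow(v), 70), ]  # unequal verse counts
  out <- aggregate_taxon_means(v)
  for (tr in c("tges", "fmean", "complexity3")) {
    oracle <- tapply_taxon_means(v, tr)
    expect_equal(out[[tr]], as.numeric(oracle[out$taxon]), tolerance = 1e-12)
  }
  out2 <- aggregate_taxon_means(v[sample(nrow(v)), ])
  expect_equal(out2, out)
})

test_that("explanatory derivations use midpoints and absolute-latitude means", {
  e <- tibble::tibble(
    taxon = c("a", "b"), length = c(11, 12), mass = c(8, 9),
    migration = c(0, 2), region = c(1, 2),
    lat_max = c(59, 40), lat_min = c(-18, -10),
    long_max = c(100, 60), long_min = c(20, -10),
    ele_max = c(4880, 2000), ele_min = c(0, 500), habitat = c(5, 3)
  )
  d <- derive_explanatory(e)
  expect_equal(d$lat_mean, c(20.5, 15))
  expect_equal(d$ele_mean, c(2440, 1250))
  expect_equal(d$lat_equator, c((59 + 18) / 2, 25))
  expect_equal(d$lat_equator_alt, abs(d$lat_mean))
  e$lat_min[1] <- 60
  expect_error(validate_explanatory(e), "lat_max")
})

test_that("cohort summaries reproduce the reference score means", {
  counts <- reference_cohort_counts()
  e <- tibble::tibble(
    migration = rep(as.integer(names(counts$migration)), counts$migration),
    habitat = rep(as.integer(names(counts$habitat)), counts$habitat)
  )
  s <- summarize_cohort(e, c("migration", "habitat"))
  expect_equal(round(s$mean[s$variable == "migration"], 1), 1.3)
  expect_equal(round(s$mean[s$variable == "habitat"], 1), 4.1)

  same <- tibble::tibble(x = rep(2, 10))
  expect_equal(summarize_cohort(same, "x")$sd, 0)
})

test_that("scaled PCA conserves total variance and fixes loading signs", {
  v <- derive_song_traits(make_verses(12, 3, 3, seed = 8))
  tt <- aggregate_taxon_means(v)
  for (s in c("all", "comp", "freq")) {
    p <- pca_scaled(tt, s)
    expect_equal(sum(p$sdev^2), length(p$subset), tolerance = 1e-10)
    expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
                 tolerance = 1e-10, ignore_attr = TRUE)
    scores <- as.matrix(p$scores[-1])
    expect_lt(max(abs(colMeans(scores))), 1e-10)
    for (j in seq_len(ncol(p$loadings))) {
      expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
    }
  }
  # the variance share of one component is its squared sdev over the total
  p <- pca_scaled(tt, "freq")
  expect_equal(tidy(p)$prop_variance, p$sdev^2 / 5)
  # duplicated variable: first component soaks up both copies
  t2 <- tt; t2$dup <- t2$fmax
  p2 <- pca_scaled(t2, c("fmax", "dup"))
  expect_equal(p2$sdev^2, c(2, 0), tolerance = 1e-10)
  t3 <- tt; t3$fmax <- 1
  expect_error(pca_scaled(t3, "freq"), "constant")
})

test_that("trait table assembles one complete row per taxon", {
  st <- small_study(seed = 21, n_taxa = 12)
  tt <- build_trait_table(st$verses, st$explanatory)
  expect_equal(nrow(tt), 12)
  expect_true(all(c(song_traits(), pc_traits(), explanatory_traits()) %in%
                    names(tt)))
  expect_false(anyNA(tt))
})
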