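test_that("OLS reproduces exact relations and the normal-equations oracle", {
  set.seed(101)
  d <- tibble::tibble(x = rnorm(20))
  d$y <- 3 + 2 * d$x
  fit <- ols_fit(d, y ~ x, standardize = FALSE)
  expect_equal(fit$coefficients$estimate, c(3, 2), tolerance = 1e-10)

  n <- 80
  X <- matrix(rnorm(n * 5), n)
  colnames(X) <- paste0("x", 1:5)
  d2 <- tibble::as_tibble(as.data.frame(X))
  d2$y <- rnorm(n)
  fit2 <- ols_fit(d2, y ~ x1 + x2 + x3 + x4 + x5, standardize = FALSE)
  Xd <- cbind(1, X)
  beta_oracle <- solve(t(Xd) %*% Xd) %*% t(Xd) %*% d2$y
  expect_equal(fit2$coefficients$estimate, as.numeric(beta_oracle),
               tolerance = 1e-8)
  # classical t-tests agree with lm
  lm_sm <- summary(stats::lm(y ~ x1 + x2 + x3 + x4 + x5, d2))$coefficients
  expect_equal(fit2$coefficients$p.value, unname(lm_sm[, 4]), tolerance = 1e-10)

  d2$x6 <- d2$x1
  expect_error(ols_fit(d2, y ~ x1 + x2 + x6, standardize = FALSE), "x6")
})

test_that("pGLS at lambda 0 is OLS and at lambda 1 matches the contrast slope", {
  tr <- simulate_tree(40, seed = 102)
  p <- sim_bm_pair(tr, 0.5)
  d <- tibble::tibble(taxon = tr$tip.label,
                      x = as.numeric(p$x[tr$tip.label]),
                      y = as.numeric(p$y[tr$tip.label]))
  f0 <- pgls_fit(d, tr, y ~ x, lambda = 0, standardize = FALSE)
  fo <- ols_fit(d, y ~ x, standardize = FALSE)
  expect_equal(f0$coefficients$estimate, fo$coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(f0$coefficients$std.error, fo$coefficients$std.error,
               tolerance = 1e-10)

  f1 <- pgls_fit(d, tr, y ~ x, lambda = 1, standardize = FALSE)
  u <- pic_contrasts(tr, p$x)$contrast
  v <- pic_contrasts(tr, p$y)$contrast
  expect_equal(f1$coefficients$estimate[2], sum(u * v) / sum(u^2),
               tolerance = 1e-8)
})

test_that("pGLS with ML lambda maximises the profile and whitens residuals", {
  tr <- simulate_tree(60, seed = 103)
  x <- simulate_trait(tr, "BM", seed = 104)
  y <- 0.4 * x + simulate_trait(tr, "lambda", lambda = 0.6, seed = 105)
  d <- tibble::tibble(taxon = tr$tip.label,
                      x = as.numeric(x[tr$tip.label]),
                      y = as.numeric(y[tr$tip.label]))
  fm <- pgls_fit(d, tr, y ~ x, lambda = "ML", standardize = FALSE)
  l0 <- pgls_fit(d, tr, y ~ x, lambda = 0, standardize = FALSE)$logL
  l1 <- pgls_fit(d, tr, y ~ x, lambda = 1, standardize = FALSE)$logL
  expect_gte(fm$logL, l0 - 1e-8)
  expect_gte(fm$logL, l1 - 1e-8)

  # agreement with nlme::gls + corPagel at a fixed lambda
  g <- nlme::gls(y ~ x, data = as.data.frame(d),
                 correlation = ape::corPagel(0.5, tr, form = ~taxon,
                                             fixed = TRUE),
                 method = "ML")
  f5 <- pgls_fit(d, tr, y ~ x, lambda = 0.5, standardize = FALSE)
  expect_equal(f5$coefficients$estimate, unname(stats::coef(g)),
               tolerance = 1e-8)
  expect_equal(f5$logL, as.numeric(stats::logLik(g)), tolerance = 1e-8)

  # whitened residuals are uncorrelated with whitened fitted values
  C <- phylo_vcv(tr)
  V <- C * fm$lambda; diag(V) <- diag(C)
  U <- chol(V)
  Xd <- cbind(1, d$x)
  res <- d$y - Xd %*% fm$coefficients$estimate
  rw <- backsolve(U, res, transpose = TRUE)
  fw <- backsolve(U, Xd %*% fm$coefficients$estimate, transpose = TRUE)
  expect_lt(abs(sum(rw * fw)) / sqrt(sum(rw^2) * sum(fw^2)), 1e-8)
})

test_that("planted slope is recovered by stepwise reduction plus pGLS", {
  tr <- simulate_tree(80, seed = 106)
  set.seed(107)
  betas <- replicate(200, {
    x <- simulate_trait(tr, "BM")
    y <- -0.3 * x + simulate_trait(tr, "BM", sigma2 = 0.1)
    d <- tibble::tibble(taxon = tr$tip.label,
                        x = as.numeric(x[tr$tip.label]),
                        y = as.numeric(y[tr$tip.label]))
    pgls_fit(d, tr, y ~ x, lambda = "ML", standardize = FALSE)$coefficients$estimate[2]
  })
  expect_lt(abs(median(betas) + 0.3), 0.05)
})

test_that("stepwise reduction keeps real predictors and sheds noise", {
  tr <- simulate_tree(80, seed = 108)
  set.seed(109)
  keep <- replicate(200, {
    X <- replicate(5, rnorm(80))
    y <- X[, 1] + rnorm(80, 0, 0.1)
    d <- tibble::as_tibble(as.data.frame(X))
    names(d) <- paste0("x", 1:5)
    d$y <- y
    st <- stepwise_reduce(d, y ~ x1 + x2 + x3 + x4 + x5, mode = "pvalue")
    c(x1 = "x1" %in% st$predictors,
      shed = sum(paste0("x", 2:5) %in% st$predictors) <= 1)
  })
  expect_equal(mean(keep["x1", ]), 1)
  expect_gte(mean(keep["shed", ]), 0.9)

  # single true predictor is never dropped
  set.seed(110)
  d1 <- tibble::tibble(x = rnorm(40))
  d1$y <- 2 * d1$x + rnorm(40, 0, 0.3)
  expect_equal(stepwise_reduce(d1, y ~ x)$predictors, "x")

  # all-noise designs collapse to the intercept in most replicates
  set.seed(111)
  empty <- replicate(300, {
    d <- tibble::as_tibble(as.data.frame(replicate(5, rnorm(80))))
    names(d) <- paste0("x", 1:5)
    d$y <- rnorm(80)
    length(stepwise_reduce(d, y ~ x1 + x2 + x3 + x4 + x5,
                           mode = "pvalue")$predictors) == 0
  })
  expect_gt(mean(empty), 0.5)
})

test_that("stepwise trace AIC is monotone non-increasing under the AIC criterion", {
  set.seed(112)
  d <- tibble::as_tibble(as.data.frame(replicate(6, rnorm(60))))
  names(d) <- paste0("x", 1:6)
  d$y <- 0.8 * d$x1 + rnorm(60)
  st <- stepwise_reduce(d, y ~ x1 + x2 + x3 + x4 + x5 + x6, mode = "aic")
  expect_true(all(diff(st$trace$aic) <= 0))
  expect_true("x1" %in% st$predictors)
})

test_that("the full trait-model chain flags planted predictors and controls nulls", {
  st <- small_study(seed = 113, n_taxa = 40)
  tt <- build_trait_table(st$verses, st$explanatory)
  tt <- tt[match(st$tree$tip.label, tt$taxon), ]
  set.seed(114)
  hits <- replicate(40, {
    y <- 0.5 * scale(tt$migration)[, 1] + 0.5 * scale(tt$lat_equator)[, 1] +
      simulate_trait(st$tree, "BM", sigma2 = 0.25)
    d <- dplyr::mutate(tt, resp = as.numeric(y))
    tm <- suppressMessages(run_trait_model(d, st$tree, "resp"))
    all(c("migration", "lat_equator") %in% tm$summary$term[tm$summary$significant])
  })
  expect_gte(mean(hits), 0.8)

  set.seed(115)
  flagged <- replicate(40, {
    d <- dplyr::mutate(tt, resp = as.numeric(simulate_trait(st$tree, "BM")))
    tm <- suppressMessages(run_trait_model(d, st$tree, "resp"))
    sum(tm$summary$significant)
  })
  expect_gte(mean(flagged <= 1), 0.75)

  # a trait identical to a predictor survives with overwhelming significance
  d <- dplyr::mutate(tt, resp = tt$habitat + 0.001 * rnorm(nrow(tt)))
  tm <- suppressMessages(run_trait_model(d, st$tree, "resp"))
  expect_true("habitat" %in% tm$summary$term)
  expect_lt(tm$summary$p.value[tm$summary$term == "habitat"], 1e-6)
})
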